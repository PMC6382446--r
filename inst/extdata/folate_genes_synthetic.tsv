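MTHFR
MTHFD1
MTR
MTRR
TCN2
SLC19A1
FOLR1
DHFR
SHMT1
TYMS
FOLPG001
FOLPG002
FOLPG003
FOLPG004
FOLPG005
FOLPG006
FOLPG007
FOLPG008
FOLPG009
FOLPG010
FOLPG011
FOLPG012
FOLPG013
FOLPG014
FOLPG015
FOLPG016
FOLPG017
FOLPG018
FOLPG019
FOLPG020
FOLPG021
FOLPG022
FOLPG023
FOLPG024
FOLPG025
FOLPG026
FOLPG027
FOLPG028
FOLPG029
FOLPG030
FOLPG031
FOLPG032
FOLPG033
FOLPG034
FOLPG035
FOLPG036
FOLPG037
FOLPG038
FOLPG039
FOLPG040
FOLPG041
FOLPG042
FOLPG043
FOLPG044
FOLPG045
FOLPG046
FOLPG047
FOLPG048
FOLPG049
FOLPG050
FOLPG051
FOLPG052
FOLPG053
FOLPG054
FOLPG055
FOLPG056
FOLPG057
FOLPG058
FOLPG059
FOLPG060
FOLPG061
FOLPG062
FOLPG063
FOLPG064
FOLPG065
FOLPG066
FOLPG067
FOLPG068
FOLPG069
FOLPG070
FOLPG071
FOLPG072
FOLPG073
FOLPG074
FOLPG075
FOLPG076
FOLPG077
FOLPG078
FOLPG079
FOLPG080
FOLPG081
FOLPG082
FOLPG083
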