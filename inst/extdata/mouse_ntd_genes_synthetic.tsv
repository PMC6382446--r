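DLC1
ITGB1
APAF1
SHROOM3
PAX3
GRHL3
VANGL1
VANGL2
CELSR1
SCRIB
MNTDG001
MNTDG002
MNTDG003
MNTDG004
MNTDG005
MNTDG006
MNTDG007
MNTDG008
MNTDG009
MNTDG010
MNTDG011
MNTDG012
MNTDG013
MNTDG014
MNTDG015
MNTDG016
MNTDG017
MNTDG018
MNTDG019
MNTDG020
MNTDG021
MNTDG022
MNTDG023
MNTDG024
MNTDG025
MNTDG026
MNTDG027
MNTDG028
MNTDG029
MNTDG030
MNTDG031
MNTDG032
MNTDG033
MNTDG034
MNTDG035
MNTDG036
MNTDG037
MNTDG038
MNTDG039
MNTDG040
MNTDG041
MNTDG042
MNTDG043
MNTDG044
MNTDG045
MNTDG046
MNTDG047
MNTDG048
MNTDG049
MNTDG050
MNTDG051
MNTDG052
MNTDG053
MNTDG054
MNTDG055
MNTDG056
MNTDG057
MNTDG058
MNTDG059
MNTDG060
MNTDG061
MNTDG062
MNTDG063
MNTDG064
MNTDG065
MNTDG066
MNTDG067
MNTDG068
MNTDG069
MNTDG070
MNTDG071
MNTDG072
MNTDG073
MNTDG074
MNTDG075
MNTDG076
MNTDG077
MNTDG078
MNTDG079
MNTDG080
MNTDG081
MNTDG082
MNTDG083
MNTDG084
MNTDG085
MNTDG086
MNTDG087
MNTDG088
MNTDG089
MNTDG090
MNTDG091
MNTDG092
MNTDG093
MNTDG094
MNTDG095
MNTDG096
MNTDG097
MNTDG098
MNTDG099
MNTDG100
MNTDG101
MNTDG102
MNTDG103
MNTDG104
MNTDG105
MNTDG106
MNTDG107
MNTDG108
MNTDG109
MNTDG110
MNTDG111
MNTDG112
MNTDG113
MNTDG114
MNTDG115
MNTDG116
MNTDG117
MNTDG118
MNTDG119
MNTDG120
MNTDG121
MNTDG122
MNTDG123
MNTDG124
MNTDG125
MNTDG126
MNTDG127
MNTDG128
MNTDG129
MNTDG130
MNTDG131
MNTDG132
MNTDG133
MNTDG134
MNTDG135
MNTDG136
MNTDG137
MNTDG138
MNTDG139
MNTDG140
MNTDG141
MNTDG142
MNTDG143
MNTDG144
MNTDG145
MNTDG146
MNTDG147
MNTDG148
MNTDG149
MNTDG150
MNTDG151
MNTDG152
MNTDG153
MNTDG154
MNTDG155
MNTDG156
MNTDG157
MNTDG158
MNTDG159
MNTDG160
MNTDG161
MNTDG162
MNTDG163
MNTDG164
MNTDG165
MNTDG166
MNTDG167
MNTDG168
MNTDG169
MNTDG170
MNTDG171
MNTDG172
MNTDG173
MNTDG174
MNTDG175
MNTDG176
MNTDG177
MNTDG178
MNTDG179
MNTDG180
MNTDG181
MNTDG182
MNTDG183
MNTDG184
MNTDG185
MNTDG186
MNTDG187
MNTDG188
MNTDG189
MNTDG190
MNTDG191
MNTDG192
MNTDG193
MNTDG194
MNTDG195
MNTDG196
MNTDG197
MNTDG198
MNTDG199
MNTDG200
MNTDG201
MNTDG202
MNTDG203
MNTDG204
MNTDG205
MNTDG206
MNTDG207
MNTDG208
MNTDG209
MNTDG210
MNTDG211
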