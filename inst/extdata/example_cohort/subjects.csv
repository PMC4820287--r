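subject_id
S00001
S00002
S00003
S00004
S00005
S00006
S00007
S00008
S00009
S00010
S00011
S00012
S00013
S00014
S00015
S00016
S00017
S00018
S00019
S00020
S00021
S00022
S00023
S00024
S00025
S00026
S00027
S00028
S00029
S00030
S00031
S00032
S00033
S00034
S00035
S00036
S00037
S00038
S00039
S00040
S00041
S00042
S00043
S00044
S00045
S00046
S00047
S00048
S00049
S00050
S00051
S00052
S00053
S00054
S00055
S00056
S00057
S00058
S00059
S00060
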