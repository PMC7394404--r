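H SYNM001001
M rows = ACDEFGHIKLMNPQRSTVWY, cols = ACDEFGHIKLMNPQRSTVWY
1.370958
-0.3066386 -1.781308
0.2059986 -0.3610573 0.7581632
-0.3672346 0.1852306 0.5818237 1.399737
1.512707 0.2579214 0.08844023 -0.1208965 -1.194329
1.200965 1.044751 -1.003209 1.848482 -0.6667734 0.1055138
-1.493625 -1.470436 0.1247024 -0.9966391 -0.001822614 -0.4282589 -0.6136716
-0.0861073 -0.887679 -0.444684 -0.02944488 -0.4138688 1.113386 -0.4809928 -0.433169
-0.1755259 -1.071782 0.1632069 -0.3627384 0.5900135 1.432422 -0.9926925 0.4546503 0.08489806
0.1514559 -0.584109 0.3688067 0.2946543 -0.2792594 -1.336237 0.7007488 0.5541966 -0.8363066 -1.594588
-2.000929 0.3337772 1.171325 2.059539 -1.376862 -1.150856 -0.7058214 -1.054056 -0.6457437 -0.185378 -1.201222
0.3856679 -0.3515129 -0.5217961 -1.068131 0.4283659 -0.1740182 0.5156677 -0.2343653 -0.6585034 1.250237 -0.2717637 0.947952
-0.7292173 0.9980689 1.258482 1.248864 -1.380637 2.049961 1.016873 -0.02671746 0.7036078 -0.9713852 -1.096156 0.04905045 -1.198496
0.8727554 0.969545 0.3838467 -1.851556 -0.05399674 1.064773 0.813195 -0.1908165 -2.69993 0.06096664 0.5737517 0.04580358 0.1574125 0.4315654
0.824074 -1.662629 -0.5693063 0.6355138 0.04372201 0.3480123 2.459594 -0.8183803  -2.1132 0.2736953 -0.6875968 0.4460411 -0.8123847 2.212055 -0.123706
-0.004620768 0.7602422 0.03899091 0.7350721 -0.1464726 -0.05788734 0.4823695 0.9929436 -1.246395 -0.03348752 -0.07096218 -0.7589207 -1.034359 -0.630732 0.5868077 -0.4163227
-0.4845954 0.1891288 0.05100633 -0.0002406689 1.809382 -0.825328  1.14547 0.03157319 -0.8352058 -0.06876365 0.7467717 -0.4255187 -0.7720822 0.1527641 0.9885968 -0.07345833 -1.387027
-0.02142707 0.6704981 -0.434617 -1.11388 0.607106 0.275457 1.157347 -1.682481 0.08731909 1.353362 0.7241738 -0.8325528 0.7325285 -0.8719269 -0.4533975 1.187534 -0.2901453 0.8285461
-0.8488157 -1.08852 -0.4842906 -0.3363112 -0.1533579 -0.2432472 1.892202 -1.385998 -0.4148243 0.3490815 1.628442 0.0885219 1.239151 -1.644556 1.446357 -0.6905602 -0.2764311 -1.109419 0.1338693
2.422163 -1.076829 0.4859411 1.388522 -0.1956568 -0.2181748 -0.304778 0.5978327 1.397429 0.6876198 0.320188 -0.3018699 0.4983487 -0.5495369 -0.2792565 1.096513 0.4420131 0.2410163 -0.2556077 0.9310329
//
H SYNM002001
M rows = ACDEFGHIKLMNPQRSTVWY, cols = ACDEFGHIKLMNPQRSTVWY
1.334913
0.7959559 -1.45353
1.357896 0.3345028 1.429338
0.8143659 2.098031 0.3009801 -1.083075
-0.2256037 -1.92495 -1.439229 -1.469658 0.7618634
1.029141 0.9147749 -0.002456267 0.1360096 -0.7201535 -0.1981243
1.597413 -0.3335854 0.6049859 0.2242412 3.229069 0.9204526 -1.206539
-0.2284335 -0.3478281 0.5321286 1.607235 0.5138145 1.382373 0.763097 -0.6245845
0.5877163 0.0896423 0.9672617 0.07881235  -1.5687 -2.007823 0.5409735 -0.0733766 -0.5710184
0.05357102 -0.4348984 -1.737297 -1.263696 0.4063085 -1.459654 1.048457 -1.346431 -0.1935706 -0.002335957
-0.2484829 0.4223204 0.9876533 0.8355682 -0.6605219 1.564069 -1.622976 0.8638964 -0.5116028 -1.917365 -1.865814
1.001113 0.747452 -0.6265748 0.3952237 -0.892168 0.6308184 -0.4327052 0.4521386 0.367999 -0.2703875 0.4655126 0.5743562
0.8029327 -0.5734769 -1.928125 0.6643908 -1.60254  -1.3546 -3.017933 0.8312378 0.2510971 0.4622935 0.8447922 -0.04197152 -1.105576
-0.5991819 1.256907 0.05350801 0.7280925 1.561098 0.2656248 1.076726 0.2106979 -1.511674 0.02240226 0.7181362 0.489457 -0.1738883 -1.217699
0.002772185 -1.32821 1.179696 -0.592805 1.199978 -0.4750337 -0.5750571 -0.03122602 -0.358057 -0.3566011 -0.8776644 -1.212897 0.6132866 -0.8062033 -1.376457
0.2946924 0.3927413 -1.000844 -0.3257271 -1.008349 -0.6354315 -1.209841 -1.116464 0.6298812 -0.2725216 -0.2588412 1.729558 -0.05839217 -0.5370638 0.7472867 -0.4872578
0.3286404 1.466511 -0.3560095 0.2614676 0.3333289 1.422193 0.6638766 -1.073655 -0.6969018 -0.7461305 0.1415729 -0.003947221 0.3679375 -0.6573429 -0.3763467 0.7413601 -0.09960676
-0.9165347 1.709689 -1.168101 -1.781036 -2.253132 0.651126 -0.5328326 -0.2755594 0.289627 -0.4664841 -1.60806 -1.949784 -0.3406999 0.1747255 -2.277778 0.2905245 0.4223064 1.294737
0.6046036 -0.01914077 -0.07971435 0.1159845 0.7441734 -0.4312906 -0.499529 -0.8651621 -0.9577573   0.3268 1.547372 -0.9688596 -0.1884404 -1.030001 0.9080864 -0.3173819 0.179004 0.3480282 -1.054279
-0.2283426 0.6753556 -1.233245 -1.199962 0.7658666 -0.5880979 -0.6602958 0.1130135 -0.3203988 1.866381 0.2595315 0.1615601 0.9310749 -0.05994675 0.0487397 -1.072875 -2.292971 -1.207207 0.1141094 -1.033297
//
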