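>980 stem=11 source=natural cols=1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23
AGUAACGGGGAUUUACCAGCCCG
>3SUX stem=11 source=natural cols=1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23
AGUAACGGGGAUUUACCAGCUCG
>4LVV stem=11 source=natural cols=1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23
AGUAAUGGGAUGUCAC-CGUCCG
>148 stem=11 source=natural cols=1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23
AGCAACGGGGAUUUACCAGCCCG
>158 stem=11 source=natural cols=1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23
AGUAACAGGGAUUUACCAGCCCG
>593 stem=11 source=natural cols=1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23
AGUAACGGGAAUUUACCAGUCCG
>894 stem=11 source=natural cols=1,2,3,4,5,6,6.1,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23
AGUAACGGGGAAUUUACCAGUCCG
>980.8 stem=11 source=artificial cols=1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23
AGUAACGGGGAUUUACCAGCCUG
>980.11 stem=11 source=artificial cols=1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23
AGUAACGCGGAUUUACCAGCCGG
>4LVV.1 stem=11 source=artificial cols=1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23
AGUAAUGGGUUGUCAC-CGACCG
>4LVV.2 stem=11 source=artificial cols=1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23
AGUAAUGGGAAGUCAC-CGUCCG
>4LVV.3 stem=11 source=artificial cols=1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23
AGUAAUGGGUAGUCAC-CGACCG
>488.1 stem=11 source=artificial cols=1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23
AGUAAUGGGGAGUCAC-CGCCCG
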