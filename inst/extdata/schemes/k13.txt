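# search scheme for k = 13, p = 14 parts
k 13
{1,2,3,4,5,6,7,8,9,10,11,12,13,14} {0,0,0,0,0,0,0,0,0,0,0,0,0,0} {0,13,13,13,13,13,13,13,13,13,13,13,13,13}
{2,3,4,5,6,7,8,9,10,11,12,13,14,1} {0,0,0,0,0,0,0,0,0,0,0,0,0,0} {0,13,13,13,13,13,13,13,13,13,13,13,13,13}
{3,4,5,6,7,8,9,10,11,12,13,14,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0,0} {0,13,13,13,13,13,13,13,13,13,13,13,13,13}
{4,5,6,7,8,9,10,11,12,13,14,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0,0} {0,13,13,13,13,13,13,13,13,13,13,13,13,13}
{5,6,7,8,9,10,11,12,13,14,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0,0} {0,13,13,13,13,13,13,13,13,13,13,13,13,13}
{6,7,8,9,10,11,12,13,14,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0,0} {0,13,13,13,13,13,13,13,13,13,13,13,13,13}
{7,8,9,10,11,12,13,14,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0,0} {0,13,13,13,13,13,13,13,13,13,13,13,13,13}
{8,9,10,11,12,13,14,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0,0} {0,13,13,13,13,13,13,13,13,13,13,13,13,13}
{9,10,11,12,13,14,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0,0} {0,13,13,13,13,13,13,13,13,13,13,13,13,13}
{10,11,12,13,14,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0,0} {0,13,13,13,13,13,13,13,13,13,13,13,13,13}
{11,12,13,14,10,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0,0} {0,13,13,13,13,13,13,13,13,13,13,13,13,13}
{12,13,14,11,10,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0,0} {0,13,13,13,13,13,13,13,13,13,13,13,13,13}
{13,14,12,11,10,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0,0} {0,13,13,13,13,13,13,13,13,13,13,13,13,13}
{14,13,12,11,10,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0,0} {0,13,13,13,13,13,13,13,13,13,13,13,13,13}
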