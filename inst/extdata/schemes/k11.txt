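# search scheme for k = 11, p = 12 parts
k 11
{1,2,3,4,5,6,7,8,9,10,11,12} {0,0,0,0,0,0,0,0,0,0,0,0} {0,11,11,11,11,11,11,11,11,11,11,11}
{2,3,4,5,6,7,8,9,10,11,12,1} {0,0,0,0,0,0,0,0,0,0,0,0} {0,11,11,11,11,11,11,11,11,11,11,11}
{3,4,5,6,7,8,9,10,11,12,2,1} {0,0,0,0,0,0,0,0,0,0,0,0} {0,11,11,11,11,11,11,11,11,11,11,11}
{4,5,6,7,8,9,10,11,12,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0} {0,11,11,11,11,11,11,11,11,11,11,11}
{5,6,7,8,9,10,11,12,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0} {0,11,11,11,11,11,11,11,11,11,11,11}
{6,7,8,9,10,11,12,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0} {0,11,11,11,11,11,11,11,11,11,11,11}
{7,8,9,10,11,12,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0} {0,11,11,11,11,11,11,11,11,11,11,11}
{8,9,10,11,12,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0} {0,11,11,11,11,11,11,11,11,11,11,11}
{9,10,11,12,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0} {0,11,11,11,11,11,11,11,11,11,11,11}
{10,11,12,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0} {0,11,11,11,11,11,11,11,11,11,11,11}
{11,12,10,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0} {0,11,11,11,11,11,11,11,11,11,11,11}
{12,11,10,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0} {0,11,11,11,11,11,11,11,11,11,11,11}
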