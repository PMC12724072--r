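# search scheme for k = 12, p = 13 parts
k 12
{1,2,3,4,5,6,7,8,9,10,11,12,13} {0,0,0,0,0,0,0,0,0,0,0,0,0} {0,12,12,12,12,12,12,12,12,12,12,12,12}
{2,3,4,5,6,7,8,9,10,11,12,13,1} {0,0,0,0,0,0,0,0,0,0,0,0,0} {0,12,12,12,12,12,12,12,12,12,12,12,12}
{3,4,5,6,7,8,9,10,11,12,13,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0} {0,12,12,12,12,12,12,12,12,12,12,12,12}
{4,5,6,7,8,9,10,11,12,13,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0} {0,12,12,12,12,12,12,12,12,12,12,12,12}
{5,6,7,8,9,10,11,12,13,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0} {0,12,12,12,12,12,12,12,12,12,12,12,12}
{6,7,8,9,10,11,12,13,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0} {0,12,12,12,12,12,12,12,12,12,12,12,12}
{7,8,9,10,11,12,13,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0} {0,12,12,12,12,12,12,12,12,12,12,12,12}
{8,9,10,11,12,13,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0} {0,12,12,12,12,12,12,12,12,12,12,12,12}
{9,10,11,12,13,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0} {0,12,12,12,12,12,12,12,12,12,12,12,12}
{10,11,12,13,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0} {0,12,12,12,12,12,12,12,12,12,12,12,12}
{11,12,13,10,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0} {0,12,12,12,12,12,12,12,12,12,12,12,12}
{12,13,11,10,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0} {0,12,12,12,12,12,12,12,12,12,12,12,12}
{13,12,11,10,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0,0,0} {0,12,12,12,12,12,12,12,12,12,12,12,12}
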