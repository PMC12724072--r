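# search scheme for k = 10, p = 11 parts
k 10
{1,2,3,4,5,6,7,8,9,10,11} {0,0,0,0,0,0,0,0,0,0,0} {0,10,10,10,10,10,10,10,10,10,10}
{2,3,4,5,6,7,8,9,10,11,1} {0,0,0,0,0,0,0,0,0,0,0} {0,10,10,10,10,10,10,10,10,10,10}
{3,4,5,6,7,8,9,10,11,2,1} {0,0,0,0,0,0,0,0,0,0,0} {0,10,10,10,10,10,10,10,10,10,10}
{4,5,6,7,8,9,10,11,3,2,1} {0,0,0,0,0,0,0,0,0,0,0} {0,10,10,10,10,10,10,10,10,10,10}
{5,6,7,8,9,10,11,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0} {0,10,10,10,10,10,10,10,10,10,10}
{6,7,8,9,10,11,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0} {0,10,10,10,10,10,10,10,10,10,10}
{7,8,9,10,11,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0} {0,10,10,10,10,10,10,10,10,10,10}
{8,9,10,11,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0} {0,10,10,10,10,10,10,10,10,10,10}
{9,10,11,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0} {0,10,10,10,10,10,10,10,10,10,10}
{10,11,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0} {0,10,10,10,10,10,10,10,10,10,10}
{11,10,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0,0} {0,10,10,10,10,10,10,10,10,10,10}
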