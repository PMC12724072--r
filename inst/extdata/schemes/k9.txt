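# search scheme for k = 9, p = 10 parts
k 9
{1,2,3,4,5,6,7,8,9,10} {0,0,0,0,0,0,0,0,0,0} {0,9,9,9,9,9,9,9,9,9}
{2,3,4,5,6,7,8,9,10,1} {0,0,0,0,0,0,0,0,0,0} {0,9,9,9,9,9,9,9,9,9}
{3,4,5,6,7,8,9,10,2,1} {0,0,0,0,0,0,0,0,0,0} {0,9,9,9,9,9,9,9,9,9}
{4,5,6,7,8,9,10,3,2,1} {0,0,0,0,0,0,0,0,0,0} {0,9,9,9,9,9,9,9,9,9}
{5,6,7,8,9,10,4,3,2,1} {0,0,0,0,0,0,0,0,0,0} {0,9,9,9,9,9,9,9,9,9}
{6,7,8,9,10,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0} {0,9,9,9,9,9,9,9,9,9}
{7,8,9,10,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0} {0,9,9,9,9,9,9,9,9,9}
{8,9,10,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0} {0,9,9,9,9,9,9,9,9,9}
{9,10,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0} {0,9,9,9,9,9,9,9,9,9}
{10,9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0,0} {0,9,9,9,9,9,9,9,9,9}
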