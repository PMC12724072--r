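# search scheme for k = 8, p = 9 parts
k 8
{1,2,3,4,5,6,7,8,9} {0,0,0,0,0,0,0,0,0} {0,8,8,8,8,8,8,8,8}
{2,3,4,5,6,7,8,9,1} {0,0,0,0,0,0,0,0,0} {0,8,8,8,8,8,8,8,8}
{3,4,5,6,7,8,9,2,1} {0,0,0,0,0,0,0,0,0} {0,8,8,8,8,8,8,8,8}
{4,5,6,7,8,9,3,2,1} {0,0,0,0,0,0,0,0,0} {0,8,8,8,8,8,8,8,8}
{5,6,7,8,9,4,3,2,1} {0,0,0,0,0,0,0,0,0} {0,8,8,8,8,8,8,8,8}
{6,7,8,9,5,4,3,2,1} {0,0,0,0,0,0,0,0,0} {0,8,8,8,8,8,8,8,8}
{7,8,9,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0} {0,8,8,8,8,8,8,8,8}
{8,9,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0} {0,8,8,8,8,8,8,8,8}
{9,8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0,0} {0,8,8,8,8,8,8,8,8}
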