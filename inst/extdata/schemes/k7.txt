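# search scheme for k = 7, p = 8 parts
k 7
{1,2,3,4,5,6,7,8} {0,0,0,0,0,0,0,0} {0,7,7,7,7,7,7,7}
{2,3,4,5,6,7,8,1} {0,0,0,0,0,0,0,0} {0,7,7,7,7,7,7,7}
{3,4,5,6,7,8,2,1} {0,0,0,0,0,0,0,0} {0,7,7,7,7,7,7,7}
{4,5,6,7,8,3,2,1} {0,0,0,0,0,0,0,0} {0,7,7,7,7,7,7,7}
{5,6,7,8,4,3,2,1} {0,0,0,0,0,0,0,0} {0,7,7,7,7,7,7,7}
{6,7,8,5,4,3,2,1} {0,0,0,0,0,0,0,0} {0,7,7,7,7,7,7,7}
{7,8,6,5,4,3,2,1} {0,0,0,0,0,0,0,0} {0,7,7,7,7,7,7,7}
{8,7,6,5,4,3,2,1} {0,0,0,0,0,0,0,0} {0,7,7,7,7,7,7,7}
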