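# search scheme for k = 6, p = 7 parts
k 6
{1,2,3,4,5,6,7} {0,0,0,0,0,0,0} {0,6,6,6,6,6,6}
{2,3,4,5,6,7,1} {0,0,0,0,0,0,0} {0,6,6,6,6,6,6}
{3,4,5,6,7,2,1} {0,0,0,0,0,0,0} {0,6,6,6,6,6,6}
{4,5,6,7,3,2,1} {0,0,0,0,0,0,0} {0,6,6,6,6,6,6}
{5,6,7,4,3,2,1} {0,0,0,0,0,0,0} {0,6,6,6,6,6,6}
{6,7,5,4,3,2,1} {0,0,0,0,0,0,0} {0,6,6,6,6,6,6}
{7,6,5,4,3,2,1} {0,0,0,0,0,0,0} {0,6,6,6,6,6,6}
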