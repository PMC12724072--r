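# search scheme for k = 5, p = 6 parts
k 5
{1,2,3,4,5,6} {0,0,0,0,0,0} {0,5,5,5,5,5}
{2,3,4,5,6,1} {0,0,0,0,0,0} {0,5,5,5,5,5}
{3,4,5,6,2,1} {0,0,0,0,0,0} {0,5,5,5,5,5}
{4,5,6,3,2,1} {0,0,0,0,0,0} {0,5,5,5,5,5}
{5,6,4,3,2,1} {0,0,0,0,0,0} {0,5,5,5,5,5}
{6,5,4,3,2,1} {0,0,0,0,0,0} {0,5,5,5,5,5}
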