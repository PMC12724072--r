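# search scheme for k = 3, p = 4 parts
k 3
{1,2,3,4} {0,0,0,0} {0,3,3,3}
{2,3,4,1} {0,0,0,0} {0,3,3,3}
{3,4,2,1} {0,0,0,0} {0,3,3,3}
{4,3,2,1} {0,0,0,0} {0,3,3,3}
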