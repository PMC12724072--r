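# search scheme for k = 2, p = 3 parts
k 2
{1,2,3} {0,0,0} {0,2,2}
{2,3,1} {0,0,0} {0,2,2}
{3,2,1} {0,0,0} {0,2,2}
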