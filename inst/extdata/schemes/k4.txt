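# search scheme for k = 4, p = 5 parts
k 4
{1,2,3,4,5} {0,0,0,0,0} {0,4,4,4,4}
{2,3,4,5,1} {0,0,0,0,0} {0,4,4,4,4}
{3,4,5,2,1} {0,0,0,0,0} {0,4,4,4,4}
{4,5,3,2,1} {0,0,0,0,0} {0,4,4,4,4}
{5,4,3,2,1} {0,0,0,0,0} {0,4,4,4,4}
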