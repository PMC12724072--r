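# search scheme for k = 1, p = 2 parts
k 1
{1,2} {0,0} {0,1}
{2,1} {0,0} {0,1}
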