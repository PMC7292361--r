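1 read1 1 011 ###
1 read2 2 0010 ####
1 read3 3 101 ###
1 read4 1 10 ##
2 read5 1 01 4 01 ####
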