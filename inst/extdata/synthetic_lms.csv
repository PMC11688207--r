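sex,month,L,M,S
female,120,-1.4,16,0.11
female,121,-1.4,16.04,0.11
female,122,-1.4,16.08,0.11
female,123,-1.4,16.12,0.11
female,124,-1.4,16.16,0.11
female,125,-1.4,16.2,0.11
female,126,-1.4,16.24,0.11
female,127,-1.4,16.28,0.11
female,128,-1.4,16.32,0.11
female,129,-1.4,16.36,0.11
female,130,-1.4,16.4,0.11
female,131,-1.4,16.44,0.11
female,132,-1.4,16.48,0.11
female,133,-1.4,16.52,0.11
female,134,-1.4,16.56,0.11
female,135,-1.4,16.6,0.11
female,136,-1.4,16.64,0.11
female,137,-1.4,16.68,0.11
female,138,-1.4,16.72,0.11
female,139,-1.4,16.76,0.11
female,140,-1.4,16.8,0.11
female,141,-1.4,16.84,0.11
female,142,-1.4,16.88,0.11
female,143,-1.4,16.92,0.11
female,144,-1.4,16.96,0.11
female,145,-1.4,17,0.11
female,146,-1.4,17.04,0.11
female,147,-1.4,17.08,0.11
female,148,-1.4,17.12,0.11
female,149,-1.4,17.16,0.11
female,150,-1.4,17.2,0.11
female,151,-1.4,17.24,0.11
female,152,-1.4,17.28,0.11
female,153,-1.4,17.32,0.11
female,154,-1.4,17.36,0.11
female,155,-1.4,17.4,0.11
female,156,-1.4,17.44,0.11
female,157,-1.4,17.48,0.11
female,158,-1.4,17.52,0.11
female,159,-1.4,17.56,0.11
female,160,-1.4,17.6,0.11
female,161,-1.4,17.64,0.11
female,162,-1.4,17.68,0.11
female,163,-1.4,17.72,0.11
female,164,-1.4,17.76,0.11
female,165,-1.4,17.8,0.11
female,166,-1.4,17.84,0.11
female,167,-1.4,17.88,0.11
female,168,-1.4,17.92,0.11
female,169,-1.4,17.96,0.11
female,170,-1.4,18,0.11
female,171,-1.4,18.04,0.11
female,172,-1.4,18.08,0.11
female,173,-1.4,18.12,0.11
female,174,-1.4,18.16,0.11
female,175,-1.4,18.2,0.11
female,176,-1.4,18.24,0.11
female,177,-1.4,18.28,0.11
female,178,-1.4,18.32,0.11
female,179,-1.4,18.36,0.11
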