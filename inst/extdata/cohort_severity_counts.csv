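organ,category,count
pancreas,normal,7
pancreas,mild,15
pancreas,moderate,15
pancreas,severe,2
heart,normal,30
heart,mild,0
heart,moderate,6
heart,severe,3
liver,normal,2
liver,mild,11
liver,moderate,11
liver,severe,15
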