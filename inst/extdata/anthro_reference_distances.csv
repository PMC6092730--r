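pair,real_mm,virtual_mm,abs_diff_mm
Bar1-Bar2,13.5,12.0,1.5
Bar1-Bar3,28.0,29.3,1.3
Bar1-Bar4,76.0,78.5,2.5
Bar1-Bar5,184.5,181.5,3.0
Bar2-Bar3,15.5,17.0,1.5
Bar2-Bar4,64.5,66.3,1.8
Bar2-Bar5,167.5,170.5,3.0
Bar3-Bar4,48.4,47.2,1.2
Bar3-Bar5,156.0,157.5,1.5
Bar4-Bar5,104.5,106.8,2.3
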