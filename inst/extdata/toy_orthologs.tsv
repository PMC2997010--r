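GA_g01	GB_g01
GA_g02	GB_g02
GA_g03	GB_g03
GA_g04	GB_g04
GA_g05	GB_g05
GA_g06	GB_g06
GA_g07	GB_g07
GA_g08	GB_g08
GA_g09	GB_g09
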