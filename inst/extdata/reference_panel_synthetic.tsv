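peptide_id	origin
REF01	synthetic
REF02	synthetic
REF03	synthetic
REF04	synthetic
REF05	synthetic
REF06	synthetic
REF07	synthetic
REF08	synthetic
REF09	synthetic
REF10	synthetic
REF11	synthetic
REF12	synthetic
REF13	synthetic
REF14	synthetic
REF15	synthetic
REF16	synthetic
REF17	synthetic
REF18	synthetic
REF19	synthetic
REF20	synthetic
REF21	synthetic
REF22	synthetic
REF23	synthetic
REF24	synthetic
REF25	synthetic
REF26	synthetic
REF27	synthetic
REF28	synthetic
REF29	synthetic
REF30	synthetic
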