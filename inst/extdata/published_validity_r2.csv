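variable,r2,published_group
ARA,0.94,super-clean
C1H,0.86,clean
KA23,0.93,super-clean
KA34,0.91,super-clean
KA45,0.91,super-clean
KA56,0.91,super-clean
KA67,0.64,semi-clean
RRA23,0.86,clean
RRA34,0.88,clean
RRA45,0.86,clean
RRA56,0.86,clean
RRA67,0.70,semi-clean
ST23,0.84,clean
ST34,0.82,clean
ST45,0.70,semi-clean
ST56,0.73,semi-clean
ST67,0.57,semi-clean
TR,0.99,super-clean
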