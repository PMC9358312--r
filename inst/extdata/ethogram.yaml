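chimpanzee:
  chi01: visual
  chi02: visual
  chi03: visual
  chi04: visual
  chi05: visual
  chi06: visual
  chi07: visual
  chi08: visual
  chi09: visual
  chi10: visual
  chi11: visual
  chi12: non_visual
  chi13: non_visual
  chi14: non_visual
  chi15: non_visual
  chi16: non_visual
  chi17: non_visual
  chi18: non_visual
orangutan:
  ora01: visual
  ora02: visual
  ora03: visual
  ora04: visual
  ora05: visual
  ora06: visual
  ora07: visual
  ora08: visual
  ora09: visual
  ora10: visual
  ora11: non_visual
  ora12: non_visual
  ora13: non_visual
  ora14: non_visual
  ora15: non_visual
  ora16: non_visual
  ora17: non_visual
siamang:
  sia01: visual
  sia02: visual
  sia03: visual
  sia04: visual
  sia05: visual
  sia06: visual
  sia07: visual
  sia08: visual
  sia09: non_visual
  sia10: non_visual
  sia11: non_visual
  sia12: non_visual
  sia13: non_visual
  sia14: non_visual
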