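{
  "note": "Counts of GM categories by recording-age period and income group for the GMOS-R normative cohort (n = 1983), transcribed from the published cohort-composition table. Categories: normal (N), poor_repertoire (PR), cramped_synchronized (CS), chaotic (CH).",
  "periods": [
    {"period": "extremely_preterm",
     "LMIC": {"normal": 0, "poor_repertoire": 0, "cramped_synchronized": 0, "chaotic": 0},
     "UMIC": {"normal": 0, "poor_repertoire": 8, "cramped_synchronized": 0, "chaotic": 0},
     "HIC":  {"normal": 5, "poor_repertoire": 3, "cramped_synchronized": 0, "chaotic": 0}},
    {"period": "very_preterm",
     "LMIC": {"normal": 2, "poor_repertoire": 4, "cramped_synchronized": 0, "chaotic": 0},
     "UMIC": {"normal": 1, "poor_repertoire": 5, "cramped_synchronized": 1, "chaotic": 0},
     "HIC":  {"normal": 35, "poor_repertoire": 134, "cramped_synchronized": 3, "chaotic": 0}},
    {"period": "moderate_preterm",
     "LMIC": {"normal": 1, "poor_repertoire": 3, "cramped_synchronized": 0, "chaotic": 0},
     "UMIC": {"normal": 3, "poor_repertoire": 9, "cramped_synchronized": 0, "chaotic": 0},
     "HIC":  {"normal": 35, "poor_repertoire": 150, "cramped_synchronized": 32, "chaotic": 1}},
    {"period": "late_preterm",
     "LMIC": {"normal": 6, "poor_repertoire": 10, "cramped_synchronized": 0, "chaotic": 1},
     "UMIC": {"normal": 14, "poor_repertoire": 29, "cramped_synchronized": 7, "chaotic": 2},
     "HIC":  {"normal": 94, "poor_repertoire": 180, "cramped_synchronized": 78, "chaotic": 16}},
    {"period": "term",
     "LMIC": {"normal": 9, "poor_repertoire": 26, "cramped_synchronized": 6, "chaotic": 1},
     "UMIC": {"normal": 28, "poor_repertoire": 76, "cramped_synchronized": 16, "chaotic": 2},
     "HIC":  {"normal": 71, "poor_repertoire": 176, "cramped_synchronized": 78, "chaotic": 3}},
    {"period": "post_term",
     "LMIC": {"normal": 32, "poor_repertoire": 48, "cramped_synchronized": 7, "chaotic": 0},
     "UMIC": {"normal": 32, "poor_repertoire": 109, "cramped_synchronized": 11, "chaotic": 0},
     "HIC":  {"normal": 115, "poor_repertoire": 205, "cramped_synchronized": 60, "chaotic": 0}}
  ]
}
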