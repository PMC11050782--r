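{
  "provenance_note": "World Bank income-group assignment frozen to the snapshot used when the GMOS-R normative sample was assembled (recordings June 2018 - November 2022); not a live feed. Australia and New Zealand do not appear in the alphabetical country list of the methods text but are grouped under high-income countries in the cohort-composition table; they are included here as HIC.",
  "groups": {
    "LMIC": ["Bangladesh", "Bolivia", "Cambodia", "Egypt", "India", "Iran",
             "Nepal"],
    "UMIC": ["Argentina", "Azerbaijan", "Brazil", "China", "Colombia",
             "Kazakhstan", "Mexico", "Peru", "South Africa", "Turkey"],
    "HIC": ["Australia", "Austria", "Canada", "Chile", "Czech Republic",
            "Denmark", "Germany", "Israel", "Italy", "Japan", "Netherlands",
            "New Zealand", "Norway", "Poland", "Qatar", "South Korea",
            "Spain", "Sweden", "Switzerland", "United Kingdom",
            "United States", "Uruguay"]
  },
  "aliases": {
    "USA": "United States",
    "US": "United States",
    "United States of America": "United States",
    "UK": "United Kingdom",
    "Great Britain": "United Kingdom",
    "Korea": "South Korea",
    "Republic of Korea": "South Korea",
    "The Netherlands": "Netherlands",
    "Holland": "Netherlands",
    "Czechia": "Czech Republic",
    "Türkiye": "Turkey",
    "Turkiye": "Turkey"
  }
}
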