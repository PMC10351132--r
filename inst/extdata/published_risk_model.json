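{
  "comment": "Published six-lncRNA cervical-cancer risk model (coefficients as printed; training median cutoff not published).",
  "terms": [
    {"lncrna": "AC020916.1", "coef": -0.442},
    {"lncrna": "AC079313.1", "coef": 0.933},
    {"lncrna": "AC245128.3", "coef": 0.333},
    {"lncrna": "AL135818.1", "coef": -0.861},
    {"lncrna": "LINC02818", "coef": 1.27},
    {"lncrna": "RASA2_IT1", "coef": 2.104}
  ],
  "training_median": null
}
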