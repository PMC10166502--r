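{
  "peaks_total": 400,
  "pct_peaks_with_te": 80,
  "class_composition": [
    {
      "group": "SINE",
      "count": 256,
      "percentage": 80
    },
    {
      "group": "LTR",
      "count": 30,
      "percentage": 9.375
    },
    {
      "group": "LINE",
      "count": 27,
      "percentage": 8.4375
    },
    {
      "group": "DNA",
      "count": 7,
      "percentage": 2.1875
    }
  ],
  "family_composition": [
    {
      "group": "Alu",
      "count": 243,
      "percentage": 75.9375
    },
    {
      "group": "ERVK",
      "count": 30,
      "percentage": 9.375
    },
    {
      "group": "L1",
      "count": 27,
      "percentage": 8.4375
    },
    {
      "group": "B2",
      "count": 13,
      "percentage": 4.0625
    },
    {
      "group": "hAT-Charlie",
      "count": 7,
      "percentage": 2.1875
    }
  ],
  "within_class_composition": [
    {
      "group": "Alu",
      "count": 243,
      "percentage": 94.921875
    },
    {
      "group": "B2",
      "count": 13,
      "percentage": 5.078125
    }
  ],
  "feature_composition": [
    {
      "group": "intergenic",
      "count": 361,
      "percentage": 90.25
    },
    {
      "group": "intron",
      "count": 18,
      "percentage": 4.5
    },
    {
      "group": "CDS",
      "count": 11,
      "percentage": 2.75
    },
    {
      "group": "promoter",
      "count": 9,
      "percentage": 2.25
    },
    {
      "group": "5'UTR",
      "count": 1,
      "percentage": 0.25
    }
  ],
  "ccre_composition": [
    {
      "group": "enhD",
      "count": 12,
      "percentage": 3
    },
    {
      "group": "enhP",
      "count": 7,
      "percentage": 1.75
    },
    {
      "group": "CTCF",
      "count": 4,
      "percentage": 1
    },
    {
      "group": "prom",
      "count": 2,
      "percentage": 0.5
    },
    {
      "group": "K4m3",
      "count": 1,
      "percentage": 0.25
    }
  ],
  "enrichment_class": [
    {
      "group": "SINE",
      "frequency": 0.8,
      "ratio": 0.131655,
      "zero_coverage": false,
      "enrichment": 6.076488
    },
    {
      "group": "LTR",
      "frequency": 0.09375,
      "ratio": 0.0493,
      "zero_coverage": false,
      "enrichment": 1.901623
    },
    {
      "group": "DNA",
      "frequency": 0.021875,
      "ratio": 0.01995,
      "zero_coverage": false,
      "enrichment": 1.096491
    },
    {
      "group": "LINE",
      "frequency": 0.084375,
      "ratio": 0.08184,
      "zero_coverage": false,
      "enrichment": 1.030975
    }
  ],
  "enrichment_family": [
    {
      "group": "Alu",
      "frequency": 0.759375,
      "ratio": 0.101739,
      "zero_coverage": false,
      "enrichment": 7.463952
    },
    {
      "group": "ERVK",
      "frequency": 0.09375,
      "ratio": 0.0493,
      "zero_coverage": false,
      "enrichment": 1.901623
    },
    {
      "group": "B2",
      "frequency": 0.040625,
      "ratio": 0.029916,
      "zero_coverage": false,
      "enrichment": 1.357969
    },
    {
      "group": "hAT-Charlie",
      "frequency": 0.021875,
      "ratio": 0.01995,
      "zero_coverage": false,
      "enrichment": 1.096491
    },
    {
      "group": "L1",
      "frequency": 0.084375,
      "ratio": 0.08184,
      "zero_coverage": false,
      "enrichment": 1.030975
    }
  ],
  "motif_occurrence": [
    {
      "group": "SINE",
      "count": 92,
      "percentage": 56.097561
    },
    {
      "group": "none",
      "count": 40,
      "percentage": 24.390244
    },
    {
      "group": "LTR",
      "count": 17,
      "percentage": 10.365854
    },
    {
      "group": "LINE",
      "count": 12,
      "percentage": 7.317073
    },
    {
      "group": "DNA",
      "count": 3,
      "percentage": 1.829268
    }
  ],
  "motif_hits_total": 164,
  "de_global": {
    "total": 31,
    "up": 11,
    "down": 20,
    "padj_cut": 0.05
  }
}
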