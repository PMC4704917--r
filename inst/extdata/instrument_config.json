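{
  "comment": "Declared scoring configuration for the 53-item questionnaire: item ids, scale anchors, reverse-keyed items, R18 subscale partition, and the imputation rule per instrument. Item-level keys for the borrowed instruments live in their source publications; this file declares the keys this package scores with.",
  "instruments": {
    "conscientiousness": {
      "items": ["con_01", "con_02", "con_03", "con_04", "con_05",
                "con_06", "con_07", "con_08", "con_09", "con_10",
                "con_11", "con_12", "con_13", "con_14", "con_15"],
      "scale_min": 1,
      "scale_max": 5,
      "reversed": ["con_02", "con_04", "con_06", "con_09", "con_12"],
      "impute": "midpoint"
    },
    "fear_of_negative_evaluation": {
      "items": ["fne_01", "fne_02", "fne_03", "fne_04", "fne_05"],
      "scale_min": 1,
      "scale_max": 5,
      "reversed": [],
      "impute": "item_median"
    },
    "social_desirability": {
      "items": ["sds_01", "sds_02", "sds_03", "sds_04", "sds_05",
                "sds_06", "sds_07"],
      "scale_min": 0,
      "scale_max": 1,
      "reversed": ["sds_02", "sds_05"],
      "impute": "item_median"
    },
    "cognitive_restraint": {
      "items": ["tfeq_02", "tfeq_11", "tfeq_12", "tfeq_15", "tfeq_16",
                "tfeq_18"],
      "scale_min": 1,
      "scale_max": 4,
      "reversed": [],
      "impute": "item_median"
    },
    "uncontrolled_eating": {
      "items": ["tfeq_01", "tfeq_04", "tfeq_05", "tfeq_07", "tfeq_08",
                "tfeq_09", "tfeq_13", "tfeq_14", "tfeq_17"],
      "scale_min": 1,
      "scale_max": 4,
      "reversed": [],
      "impute": "item_median"
    },
    "emotional_eating": {
      "items": ["tfeq_03", "tfeq_06", "tfeq_10"],
      "scale_min": 1,
      "scale_max": 4,
      "reversed": [],
      "impute": "item_median"
    }
  },
  "frs": {
    "scale_min": 1,
    "scale_max": 9
  },
  "frequency": {
    "breakfast_days": {"min": 0, "max": 7},
    "school_lunch_days": {"min": 0, "max": 5}
  },
  "attitude": {
    "items": ["eat_important", "comprehensible", "manageable", "meaningful"],
    "levels": ["yes", "somewhat", "no"]
  }
}
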