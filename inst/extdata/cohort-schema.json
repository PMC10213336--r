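{
  "dialect": {
    "format": "csv",
    "encoding": "UTF-8",
    "header": true,
    "boolean_tokens": ["true", "false"]
  },
  "columns": [
    {
      "name": "respondent_id",
      "type": "string",
      "min": null,
      "max": null,
      "tokens": null,
      "_row": "1"
    },
    {
      "name": "phq9_1",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "2"
    },
    {
      "name": "phq9_2",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "3"
    },
    {
      "name": "phq9_3",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "4"
    },
    {
      "name": "phq9_4",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "5"
    },
    {
      "name": "phq9_5",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "6"
    },
    {
      "name": "phq9_6",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "7"
    },
    {
      "name": "phq9_7",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "8"
    },
    {
      "name": "phq9_8",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "9"
    },
    {
      "name": "phq9_9",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "10"
    },
    {
      "name": "gad7_1",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "11"
    },
    {
      "name": "gad7_2",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "12"
    },
    {
      "name": "gad7_3",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "13"
    },
    {
      "name": "gad7_4",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "14"
    },
    {
      "name": "gad7_5",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "15"
    },
    {
      "name": "gad7_6",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "16"
    },
    {
      "name": "gad7_7",
      "type": "integer",
      "min": 0,
      "max": 3,
      "tokens": null,
      "_row": "17"
    },
    {
      "name": "fatigue",
      "type": "integer",
      "min": 0,
      "max": 10,
      "tokens": null,
      "_row": "18"
    },
    {
      "name": "qol_1",
      "type": "integer",
      "min": 1,
      "max": 5,
      "tokens": null,
      "_row": "19"
    },
    {
      "name": "qol_2",
      "type": "integer",
      "min": 1,
      "max": 5,
      "tokens": null,
      "_row": "20"
    },
    {
      "name": "age",
      "type": "numeric",
      "min": 0,
      "max": null,
      "tokens": null,
      "_row": "21"
    },
    {
      "name": "sex",
      "type": "categorical",
      "min": null,
      "max": null,
      "tokens": "male|female",
      "_row": "sex"
    },
    {
      "name": "education",
      "type": "categorical",
      "min": null,
      "max": null,
      "tokens": "below_senior|senior_or_above",
      "_row": "education"
    },
    {
      "name": "financial_status",
      "type": "categorical",
      "min": null,
      "max": null,
      "tokens": "poor|fair|good",
      "_row": "financial_status"
    },
    {
      "name": "social_media_freq",
      "type": "categorical",
      "min": null,
      "max": null,
      "tokens": "none_minimal|sometimes|often",
      "_row": "social_media_freq"
    },
    {
      "name": "diagnosis",
      "type": "categorical",
      "min": null,
      "max": null,
      "tokens": "mdd|bipolar|schizophrenia|other",
      "_row": "diagnosis"
    },
    {
      "name": "married",
      "type": "boolean",
      "min": null,
      "max": null,
      "tokens": "true|false",
      "_row": "110"
    },
    {
      "name": "employed",
      "type": "boolean",
      "min": null,
      "max": null,
      "tokens": "true|false",
      "_row": "22"
    },
    {
      "name": "rural",
      "type": "boolean",
      "min": null,
      "max": null,
      "tokens": "true|false",
      "_row": "31"
    },
    {
      "name": "physical_disease",
      "type": "boolean",
      "min": null,
      "max": null,
      "tokens": "true|false",
      "_row": "41"
    },
    {
      "name": "visit_difficulty",
      "type": "boolean",
      "min": null,
      "max": null,
      "tokens": "true|false",
      "_row": "51"
    },
    {
      "name": "medication_compliance_good",
      "type": "boolean",
      "min": null,
      "max": null,
      "tokens": "true|false",
      "_row": "61"
    }
  ]
}
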