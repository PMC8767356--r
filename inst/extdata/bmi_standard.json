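{
  "index": "BMI",
  "units": "kg/m2",
  "resolution": 0.1,
  "standards": [
    {
      "grade": "freshman",
      "gender": "male",
      "bands": [
        {"max": 13.4, "label": "low weight", "score": 80},
        {"min": 13.5, "max": 18.1, "label": "normal", "score": 100},
        {"min": 18.2, "max": 20.3, "label": "overweight", "score": 80},
        {"min": 20.4, "label": "obesity", "score": 60}
      ]
    },
    {
      "grade": "sophomore",
      "gender": "male",
      "bands": [
        {"max": 13.6, "label": "low weight", "score": 80},
        {"min": 13.7, "max": 18.4, "label": "normal", "score": 100},
        {"min": 18.5, "max": 20.4, "label": "overweight", "score": 80},
        {"min": 20.5, "label": "obesity", "score": 60}
      ]
    },
    {
      "grade": "junior",
      "gender": "male",
      "bands": [
        {"max": 17.8, "label": "low weight", "score": 80},
        {"min": 17.9, "max": 23.9, "label": "normal", "score": 100},
        {"min": 24, "max": 27.9, "label": "overweight", "score": 80},
        {"min": 28, "label": "obesity", "score": 60}
      ]
    },
    {
      "grade": "senior",
      "gender": "female",
      "bands": [
        {"max": 17.1, "label": "low weight", "score": 80},
        {"min": 17.2, "max": 23.9, "label": "normal", "score": 100},
        {"min": 24, "max": 27.9, "label": "overweight", "score": 80},
        {"min": 28, "label": "obesity", "score": 60}
      ]
    }
  ]
}
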