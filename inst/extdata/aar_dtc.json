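{
  "nodes": [
    {
      "label": "ACO",
      "theta_minutes": 45,
      "class": "endocrine"
    },
    {
      "label": "JGC",
      "theta_minutes": 45,
      "class": "endocrine"
    },
    {
      "label": "HMY",
      "theta_minutes": 45,
      "class": "endocrine"
    },
    {
      "label": "SPN",
      "theta_minutes": 45,
      "class": "endocrine"
    },
    {
      "label": "DTC",
      "theta_minutes": 45,
      "class": "endocrine"
    }
  ],
  "edges": [
    {
      "from": "JGC",
      "to": "ACO",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "HMY",
      "to": "ACO",
      "sign": "-",
      "delay_minutes": 0
    },
    {
      "from": "HMY",
      "to": "JGC",
      "sign": "-",
      "delay_minutes": 0
    },
    {
      "from": "DTC",
      "to": "JGC",
      "sign": "-",
      "delay_minutes": 0
    },
    {
      "from": "DTC",
      "to": "HMY",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "JGC",
      "to": "SPN",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "DTC",
      "to": "SPN",
      "sign": "-",
      "delay_minutes": 0
    },
    {
      "from": "ACO",
      "to": "DTC",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "HMY",
      "to": "DTC",
      "sign": "-",
      "delay_minutes": 0
    },
    {
      "from": "SPN",
      "to": "DTC",
      "sign": "+",
      "delay_minutes": 0
    }
  ]
}
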