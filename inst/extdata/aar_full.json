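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
    },
    {
      "label": "VSM",
      "theta_minutes": 45,
      "class": "endocrine"
    },
    {
      "label": "ASR",
      "theta_minutes": 3.25,
      "class": "stretch"
    },
    {
      "label": "ACR",
      "theta_minutes": 3.25,
      "class": "stretch"
    },
    {
      "label": "NTS",
      "theta_minutes": 0.5,
      "class": "nerve"
    },
    {
      "label": "SFO",
      "theta_minutes": 0.5,
      "class": "nerve"
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
      "from": "ASR",
      "to": "HMY",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "NTS",
      "to": "SPN",
      "sign": "-",
      "delay_minutes": 0
    },
    {
      "from": "SFO",
      "to": "SPN",
      "sign": "+",
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
    },
    {
      "from": "JGC",
      "to": "VSM",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "HMY",
      "to": "VSM",
      "sign": "-",
      "delay_minutes": 0
    },
    {
      "from": "SPN",
      "to": "VSM",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "DTC",
      "to": "ASR",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "VSM",
      "to": "ASR",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "DTC",
      "to": "ACR",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "VSM",
      "to": "ACR",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "ASR",
      "to": "NTS",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "ACR",
      "to": "NTS",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "JGC",
      "to": "SFO",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "DTC",
      "to": "SFO",
      "sign": "-",
      "delay_minutes": 0
    }
  ]
}
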