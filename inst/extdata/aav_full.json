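{
  "nodes": [
    {
      "label": "x_1",
      "theta_minutes": 0.5,
      "class": "intracellular"
    },
    {
      "label": "x_2",
      "theta_minutes": 0.1,
      "class": "intracellular"
    },
    {
      "label": "x_3",
      "theta_minutes": 0.1,
      "class": "intracellular"
    },
    {
      "label": "x_4",
      "theta_minutes": 0.1,
      "class": "intracellular"
    },
    {
      "label": "x_5",
      "theta_minutes": 0.1,
      "class": "intracellular"
    },
    {
      "label": "x_6",
      "theta_minutes": 0.1,
      "class": "intracellular"
    },
    {
      "label": "x_7",
      "theta_minutes": 0.1,
      "class": "intracellular"
    },
    {
      "label": "x_8",
      "theta_minutes": 0.1,
      "class": "intracellular"
    },
    {
      "label": "x_9",
      "theta_minutes": 0.1,
      "class": "intracellular"
    },
    {
      "label": "x_10",
      "theta_minutes": 0.1,
      "class": "intracellular"
    },
    {
      "label": "x_11",
      "theta_minutes": 0.1,
      "class": "intracellular"
    },
    {
      "label": "x_12",
      "theta_minutes": 0.1,
      "class": "intracellular"
    },
    {
      "label": "x_13",
      "theta_minutes": 0.1,
      "class": "intracellular"
    },
    {
      "label": "x_14",
      "theta_minutes": 0.1,
      "class": "intracellular"
    },
    {
      "label": "x_15",
      "theta_minutes": 0.1,
      "class": "intracellular"
    },
    {
      "label": "x_16",
      "theta_minutes": 45,
      "class": "endocrine"
    },
    {
      "label": "x_17",
      "theta_minutes": 45,
      "class": "endocrine"
    },
    {
      "label": "x_18",
      "theta_minutes": 0.5,
      "class": "nerve"
    },
    {
      "label": "x_19",
      "theta_minutes": 3.25,
      "class": "stretch"
    },
    {
      "label": "x_20",
      "theta_minutes": 3.25,
      "class": "stretch"
    }
  ],
  "edges": [
    {
      "from": "x_2",
      "to": "x_1",
      "sign": "-",
      "delay_minutes": 0
    },
    {
      "from": "x_3",
      "to": "x_1",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_6",
      "to": "x_2",
      "sign": "-",
      "delay_minutes": 0
    },
    {
      "from": "x_4",
      "to": "x_3",
      "sign": "-",
      "delay_minutes": 0
    },
    {
      "from": "x_5",
      "to": "x_3",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_9",
      "to": "x_3",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_7",
      "to": "x_4",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_8",
      "to": "x_4",
      "sign": "-",
      "delay_minutes": 0
    },
    {
      "from": "x_9",
      "to": "x_4",
      "sign": "-",
      "delay_minutes": 0
    },
    {
      "from": "x_6",
      "to": "x_5",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_10",
      "to": "x_6",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_13",
      "to": "x_6",
      "sign": "-",
      "delay_minutes": 0
    },
    {
      "from": "x_14",
      "to": "x_7",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_9",
      "to": "x_8",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_12",
      "to": "x_9",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_11",
      "to": "x_10",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_15",
      "to": "x_11",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_15",
      "to": "x_12",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_14",
      "to": "x_13",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_16",
      "to": "x_14",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_17",
      "to": "x_15",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_19",
      "to": "x_16",
      "sign": "+",
      "delay_minutes": 3
    },
    {
      "from": "x_18",
      "to": "x_17",
      "sign": "-",
      "delay_minutes": 0
    },
    {
      "from": "x_19",
      "to": "x_18",
      "sign": "+",
      "delay_minutes": 3
    },
    {
      "from": "x_20",
      "to": "x_18",
      "sign": "+",
      "delay_minutes": 3
    },
    {
      "from": "x_1",
      "to": "x_19",
      "sign": "+",
      "delay_minutes": 0
    },
    {
      "from": "x_1",
      "to": "x_20",
      "sign": "+",
      "delay_minutes": 0
    }
  ]
}
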