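{
  "name": "olm_single",
  "channels": [
    {
      "name": "Na",
      "gbar": 0.00485,
      "erev": 90,
      "gates": [
        {
          "name": "m",
          "power": 3,
          "vh": -58,
          "k": 2.2,
          "tau": {
            "form": "bell",
            "base": 0.05,
            "amp": 0.3,
            "v1": -45,
            "k1": 12,
            "v2": -45,
            "k2": 12
          }
        },
        {
          "name": "h",
          "power": 1,
          "vh": -67,
          "k": -3.3,
          "tau": {
            "form": "bell",
            "base": 1,
            "amp": 10,
            "v1": -50,
            "k1": 9,
            "v2": -50,
            "k2": 9
          }
        }
      ]
    },
    {
      "name": "Kdrf",
      "gbar": 0.00433,
      "erev": -95,
      "gates": [
        {
          "name": "n",
          "power": 4,
          "vh": -52,
          "k": 3.5,
          "tau": {
            "form": "bell",
            "base": 1,
            "amp": 14,
            "v1": -55,
            "k1": 12,
            "v2": -55,
            "k2": 12
          }
        }
      ]
    },
    {
      "name": "Ka",
      "gbar": 0.00731,
      "erev": -95,
      "gates": [
        {
          "name": "a",
          "power": 3,
          "vh": -35,
          "k": 7,
          "tau": {
            "form": "bell",
            "base": 0.5,
            "amp": 3,
            "v1": -40,
            "k1": 15,
            "v2": -40,
            "k2": 15
          }
        },
        {
          "name": "b",
          "power": 1,
          "vh": -60,
          "k": -6,
          "tau": {
            "form": "bell",
            "base": 10,
            "amp": 40,
            "v1": -60,
            "k1": 15,
            "v2": -60,
            "k2": 15
          }
        }
      ]
    },
    {
      "name": "M",
      "gbar": 1.91e-05,
      "erev": -95,
      "gates": [
        {
          "name": "z",
          "power": 1,
          "vh": -45,
          "k": 5,
          "tau": {
            "form": "bell",
            "base": 30,
            "amp": 500,
            "v1": -45,
            "k1": 10,
            "v2": -45,
            "k2": 10
          }
        }
      ]
    },
    {
      "name": "h",
      "gbar": 1.05263157894737e-05,
      "erev": -34,
      "gates": [
        {
          "name": "r",
          "power": 1,
          "vh": -82,
          "k": -8,
          "tau": {
            "form": "bell",
            "base": 60,
            "amp": 500,
            "v1": -80,
            "k1": 15,
            "v2": -80,
            "k2": 15
          }
        }
      ]
    }
  ],
  "area_cm2": 0.00038,
  "cm": 1,
  "leak_gbar": 8.42105263157895e-06,
  "leak_erev": -77.829,
  "bias_pA": 4,
  "v_init": -70
}
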