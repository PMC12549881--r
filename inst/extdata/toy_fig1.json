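{
  "species": [
    {
      "id": "AcCoa"
    },
    {
      "id": "Cit"
    },
    {
      "id": "Fum"
    },
    {
      "id": "Gly"
    },
    {
      "id": "Isocit"
    },
    {
      "id": "Mal"
    },
    {
      "id": "Oaa"
    },
    {
      "id": "OG"
    },
    {
      "id": "Pep"
    },
    {
      "id": "Pyr"
    },
    {
      "id": "Succ"
    }
  ],
  "reactions": [
    {
      "id": "r01",
      "substrates": {
        "AcCoa": 1,
        "Oaa": 1
      },
      "products": {
        "Cit": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r02",
      "substrates": {
        "Cit": 1
      },
      "products": {
        "Isocit": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r03",
      "substrates": {
        "Isocit": 1
      },
      "products": {
        "Cit": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r04",
      "substrates": {
        "Isocit": 1
      },
      "products": {
        "OG": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r05",
      "substrates": {
        "OG": 1
      },
      "products": {
        "Succ": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r06",
      "substrates": {
        "Succ": 1
      },
      "products": {
        "Fum": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r07",
      "substrates": {
        "Fum": 1
      },
      "products": {
        "Succ": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r08",
      "substrates": {
        "Fum": 1
      },
      "products": {
        "Mal": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r09",
      "substrates": {
        "Mal": 1
      },
      "products": {
        "Fum": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r10",
      "substrates": {
        "Mal": 1
      },
      "products": {
        "Oaa": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r11",
      "substrates": {
        "Oaa": 1
      },
      "products": {
        "Mal": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r12",
      "substrates": {
        "Isocit": 1
      },
      "products": {
        "Gly": 1,
        "Succ": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r13",
      "substrates": {
        "AcCoa": 1,
        "Gly": 1
      },
      "products": {
        "Mal": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r14",
      "substrates": {
        "Pep": 1
      },
      "products": {
        "Oaa": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r15",
      "substrates": {
        "Pep": 1
      },
      "products": {
        "Pyr": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r16",
      "substrates": {
        "Pyr": 1
      },
      "products": {
        "AcCoa": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r17",
      "substrates": {},
      "products": {
        "Pep": 1
      },
      "lb": 0,
      "ub": 1000,
      "reversible": false
    },
    {
      "id": "r18",
      "substrates": {
        "Oaa": 1
      },
      "products": {},
      "lb": 0,
      "ub": 1000,
      "reversible": false
    }
  ]
}
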