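{
  "nodes": [
    {
      "name": "C",
      "kind": "substantive",
      "role": "confounder"
    },
    {
      "name": "M_X",
      "kind": "missingness",
      "role": "none",
      "indicator_of": "X"
    },
    {
      "name": "M_Y",
      "kind": "missingness",
      "role": "none",
      "indicator_of": "Y"
    },
    {
      "name": "M_Z",
      "kind": "missingness",
      "role": "none",
      "indicator_of": "Z"
    },
    {
      "name": "X",
      "kind": "substantive",
      "role": "exposure"
    },
    {
      "name": "Y",
      "kind": "substantive",
      "role": "outcome"
    },
    {
      "name": "Z",
      "kind": "substantive",
      "role": "confounder",
      "group_members": [
        "mat_alcohol",
        "mat_smoking",
        "child_phys"
      ]
    }
  ],
  "edges": [
    [
      "C",
      "X"
    ],
    [
      "C",
      "Y"
    ],
    [
      "C",
      "Z"
    ],
    [
      "X",
      "M_X"
    ],
    [
      "X",
      "M_Y"
    ],
    [
      "X",
      "M_Z"
    ],
    [
      "X",
      "Y"
    ],
    [
      "Z",
      "M_X"
    ],
    [
      "Z",
      "M_Y"
    ],
    [
      "Z",
      "M_Z"
    ],
    [
      "Z",
      "X"
    ],
    [
      "Z",
      "Y"
    ]
  ]
}
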