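{
  "name": "kidney",
  "children": [
    {
      "name": "Stroma",
      "children": [
        {"name": "SPC"},
        {"name": "CS"},
        {"name": "MS"},
        {"name": "MesS"}
      ]
    },
    {"name": "NPC"},
    {
      "name": "Nephron",
      "children": [
        {"name": "EN"},
        {
          "name": "DN",
          "children": [
            {"name": "EDT"},
            {"name": "DT"},
            {"name": "LOH"}
          ]
        },
        {
          "name": "PN",
          "children": [
            {"name": "EPT"},
            {"name": "PT"}
          ]
        },
        {
          "name": "RC",
          "children": [
            {"name": "PEC"},
            {"name": "EPod"},
            {"name": "Pod"}
          ]
        },
        {"name": "NCC"}
      ]
    },
    {
      "name": "UrEp",
      "children": [
        {"name": "UTip"},
        {"name": "UOS"},
        {"name": "UIS"}
      ]
    },
    {"name": "Endo"}
  ]
}
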