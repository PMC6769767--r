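{
  "clones": [
    {
      "id": "C1",
      "novel_genes": [
        "T056G001",
        "T056G002",
        "T056G003",
        "T056G004",
        "T056G005",
        "T056G006",
        "T056G007",
        "T056G008",
        "T056G009",
        "T056G010",
        "T056G011",
        "T056G012",
        "T056G013",
        "T056G014",
        "T056G015",
        "T056G016",
        "T056G017",
        "T056G018",
        "T056G019",
        "T056G020",
        "T056G021",
        "T056G022",
        "T056G023",
        "T056G024",
        "T056G025",
        "T056G026",
        "T056G027",
        "T056G028",
        "T056G029",
        "T056G030",
        "T056G031",
        "T056G032",
        "T056G033",
        "T056G034",
        "T056G035",
        "T056G036",
        "T056G037",
        "T056G038",
        "T056G039",
        "T056G040",
        "T056G041",
        "T056G042",
        "T056G043",
        "T056G044",
        "T056G045",
        "T056G046",
        "T056G047",
        "T056G048",
        "T056G049",
        "T056G050",
        "T056G051",
        "T056G052",
        "T056G053",
        "T056G054",
        "T056G055",
        "T056G056",
        "T056G057",
        "T056G058",
        "T056G059",
        "T056G060",
        "T056G061",
        "T056G062",
        "T056G063",
        "T056G064",
        "T056G065",
        "T056G066",
        "T056G067",
        "T056G068",
        "T056G069",
        "T056G070",
        "T056G071",
        "T056G072",
        "T056G073",
        "T056G074",
        "T056G075",
        "T056G076",
        "T056G077",
        "T056G078",
        "T056G079",
        "T056G080",
        "T056G081",
        "T056G082",
        "T056G083",
        "T056G084",
        "T056G085",
        "T056G086",
        "T056G087",
        "T056G088",
        "T056G089",
        "T056G090",
        "T056G091",
        "T056G092",
        "T056G093",
        "T056G094",
        "T056G095",
        "T056G096",
        "T056G097",
        "T056G098",
        "T056G099",
        "T056G100",
        "T056G101",
        "T056G102",
        "T056G103",
        "T056G104",
        "T056G105",
        "T056G106",
        "T056G107",
        "T056G108",
        "T056G109",
        "T056G110",
        "T056G111",
        "T056G112",
        "T056G113",
        "T056G114",
        "T056G115",
        "T056G116"
      ]
    },
    {
      "id": "C3",
      "parent": "C1",
      "novel_genes": [
        "TP53",
        "S056G01",
        "S056G02",
        "S056G03",
        "S056G04",
        "S056G05",
        "S056G06",
        "S056G07",
        "S056G08",
        "S056G09",
        "S056G10"
      ]
    },
    {
      "id": "C2",
      "parent": "C3",
      "novel_genes": [
        "CAMK4"
      ]
    },
    {
      "id": "C4",
      "parent": "C1",
      "novel_genes": [
        "P056G1",
        "P056G2",
        "P056G3"
      ]
    }
  ],
  "samples": [
    {
      "id": "R1",
      "prevalence": {
        "C1": 0.06,
        "C4": 0.94
      }
    },
    {
      "id": "R2",
      "prevalence": {
        "C3": 0.12,
        "C4": 0.88
      }
    },
    {
      "id": "R3",
      "prevalence": {
        "C1": 0.02,
        "C2": 0.98
      }
    }
  ]
}
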