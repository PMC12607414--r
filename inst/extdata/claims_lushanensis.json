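{
  "focal": "B. lushanensis",
  "aliases": {
    "B. huangniushiensis": "B. huangnniushienensis"
  },
  "claims": [
    {
      "character": "vomerine_teeth",
      "claimed_state": "F",
      "description": "vomerine teeth absent",
      "species": ["B. acuta", "B. angka", "B. anlongensis",
        "B. baishanzuensis", "B. baolongensis", "B. binchuanensis",
        "B. binlingensis", "B. boettgeri", "B. brachykolos",
        "B. caobangensis", "B. congjiangensis", "B. changyangensis",
        "B. cheni", "B. chishuiensis", "B. daoji", "B. dupanglingensis",
        "B. gaolanensis", "B. gutu", "B. huangniushiensis",
        "B. hengshanensis", "B. hungtai", "B. jiangi", "B. kuatunensis",
        "B. leishanensis", "B. lushuiensis", "B. lini", "B. lishuiensis",
        "B. minor", "B. mirabilis", "B. mufumontana", "B. dalaolingensis",
        "B. daxuemontis", "B. obesa", "B. ombrophila", "B. pepe",
        "B. sanmingensis", "B. shuichengensis", "B. spinata",
        "B. shunhuangensis", "B. tuberogranulatus", "B. wugongensis",
        "B. wuliangshanensis", "B. wushanensis", "B. xiangnanensis",
        "B. xianjuensis", "B. xuefengmontis", "B. yaoshanensis",
        "B. yangmingensis", "B. yunkaiensis"]
    },
    {
      "character": "heels",
      "claimed_state": "T/N",
      "description": "heels just meeting or overlapping",
      "species": ["B. daiyunensis", "B. yingdeensis"]
    },
    {
      "character": "heels",
      "claimed_state": "N",
      "description": "heels just meeting",
      "species": ["B. jingdongensis", "B. jiulianensis", "B. jinggangensis",
        "B. liboensis", "B. nanlingensis", "B. omeimontis",
        "B. qianbeiensis", "B. palpebralespinosa", "B. sangzhiensis",
        "B. shimentaina", "B. tongboensis", "B. yezhongensis"]
    },
    {
      "character": "heels",
      "claimed_state": "T",
      "description": "heels overlapping",
      "species": ["B. caudoprocta", "B. fanjingmontis", "B. elongata"]
    },
    {
      "character": "toe_fringes",
      "claimed_state": "F",
      "description": "lateral fringes on toes absent",
      "species": ["B. dongguanensis", "B. fengshunensis", "B. insularis",
        "B. lichun", "B. nankunensis", "B. puningensis",
        "B. hoanglienensis", "B. fansipanensis", "B. frigida",
        "B. daweimontis"]
    },
    {
      "character": "toe_webbing",
      "claimed_state": "F",
      "description": "webbing on toes lacking",
      "species": ["B. rubrimera"]
    }
  ]
}
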