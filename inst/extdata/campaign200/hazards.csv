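"project_id","score"
"P001",3
"P002",1
"P003",2
"P004",2
"P005",5
"P006",1
"P007",5
"P008",1
"P009",3
"P010",2
"P011",5
"P012",5
"P013",2
"P014",1
"P015",3
"P016",4
"P017",4
"P018",1
"P019",5
"P020",2
"P021",5
"P022",2
"P023",3
"P024",2
"P025",1
"P026",2
"P027",2
"P028",5
"P029",1
"P030",5
"P031",5
"P032",5
"P033",5
"P034",4
"P035",2
"P036",4
"P037",5
"P038",3
"P039",2
"P040",5
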