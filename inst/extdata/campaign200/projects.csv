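"project_id","min_limit","max_limit","unit"
"P001",0,1.036,"mg_per_L"
"P002",0,1.953,"mg_per_kg"
"P003",0,1.6,"mg_per_kg"
"P004",0,0.06549,"mg_per_kg"
"P005",0,0,"mg_per_kg"
"P006",0.03495,0.1165,"mg_per_kg"
"P007",0,1.108,"mg_per_kg"
"P008",0,3.556,"mg_per_L"
"P009",0,0,"mg_per_kg"
"P010",0,0.3599,"mg_per_kg"
"P011",0,1.607,"mg_per_kg"
"P012",0,1.063,"mg_per_kg"
"P013",0,3.637,"mg_per_kg"
"P014",0,0.5081,"mg_per_kg"
"P015",0,1.003,"mg_per_kg"
"P016",0,0.6441,"mg_per_kg"
"P017",0,1.115,"mg_per_kg"
"P018",0,0.1804,"mg_per_kg"
"P019",0,2.145,"mg_per_kg"
"P020",0,0.3101,"mg_per_kg"
"P021",0,0.6542,"mg_per_L"
"P022",0.1392,0.464,"mg_per_kg"
"P023",9.84,9.84,"mg_per_L"
"P024",0,4.83,"mg_per_kg"
"P025",0,0.4724,"mg_per_kg"
"P026",0,0.1727,"mg_per_kg"
"P027",0,0,"mg_per_kg"
"P028",0,5.374,"mg_per_kg"
"P029",0,0.8148,"mg_per_kg"
"P030",1.649,1.649,"mg_per_L"
"P031",0.5944,0.5944,"mg_per_kg"
"P032",0,5.232,"mg_per_kg"
"P033",0,0.2592,"mg_per_kg"
"P034",0,0.4879,"mg_per_L"
"P035",0,0.8272,"mg_per_kg"
"P036",0.5154,1.718,"mg_per_kg"
"P037",0,0,"mg_per_kg"
"P038",0.08454,0.2818,"mg_per_kg"
"P039",0,10.24,"mg_per_kg"
"P040",0,1.203,"mg_per_kg"
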