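"molecule_id","solvent","nucleus","shift_ppm","smiles"
"SYN000001","water","13C","83.532",""
"SYN000001","water","13C","62.255",""
"SYN000001","water","13C","55.026",""
"SYN000001","water","13C","84.609",""
"SYN000001","water","13C","187.837",""
"SYN000001","water","13C","86.239",""
"SYN000001","water","13C","196.772",""
"SYN000001","water","13C","58.185",""
"SYN000001","water","13C","82.369",""
"SYN000001","water","13C","56.408",""
"SYN000001","water","13C","81.986",""
"SYN000001","water","13C","67.075",""
"SYN000001","water","13C","77.898",""
"SYN000001","water","1H","5.507",""
"SYN000001","water","1H","5.835",""
"SYN000001","water","1H","5.494",""
"SYN000001","water","1H","5.17",""
"SYN000001","water","1H","5.792",""
"SYN000001","water","1H","5.928",""
"SYN000001","water","1H","5.6",""
"SYN000001","water","1H","5.981",""
"SYN000001","water","1H","5.096",""
"SYN000001","water","1H","5.186",""
"SYN000001","water","1H","5.328",""
"SYN000001","water","1H","6.144",""
"SYN000001","water","1H","5.995",""
"SYN000001","water","1H","5.524",""
"SYN000001","water","1H","4.589",""
"SYN000001","water","1H","5.33",""
"SYN000001","water","1H","5.481",""
"SYN000001","water","1H","5.875",""
"SYN000001","water","1H","5.621",""
"SYN000001","water","1H","5.349",""
"SYN000001","water","1H","5.78",""
"SYN000001","water","1H","5.693",""
"SYN000002","water","13C","1.786",""
"SYN000002","water","13C","5.3",""
"SYN000002","water","13C","0",""
"SYN000002","water","13C","139.134",""
"SYN000002","water","13C","139.946",""
"SYN000002","water","1H","7.797",""
"SYN000002","water","1H","8.055",""
"SYN000002","water","1H","7.693",""
"SYN000002","water","1H","7.929",""
"SYN000002","water","1H","7.837",""
"SYN000002","water","1H","7.691",""
"SYN000002","water","1H","6.651",""
"SYN000002","water","1H","7.623",""
"SYN000002","water","1H","7.788",""
"SYN000002","water","1H","7.909",""
"SYN000002","water","1H","8.308",""
"SYN000003","water","13C","45.121",""
"SYN000003","water","13C","80.716",""
"SYN000003","water","13C","69.017",""
"SYN000003","water","13C","76.186",""
"SYN000003","water","13C","35.559",""
"SYN000003","water","13C","11.314",""
"SYN000003","water","13C","87.07",""
"SYN000003","water","13C","8.762",""
"SYN000003","water","13C","83.845",""
"SYN000003","water","13C","26.7",""
"SYN000003","water","13C","75.818",""
"SYN000003","water","13C","36.511",""
"SYN000003","water","13C","91.123",""
"SYN000003","water","13C","18.732",""
"SYN000003","water","1H","8.453",""
"SYN000003","water","1H","7.869",""
"SYN000003","water","1H","8.182",""
"SYN000003","water","1H","8.02",""
"SYN000003","water","1H","8.586",""
"SYN000003","water","1H","7.637",""
"SYN000003","water","1H","8.93",""
"SYN000003","water","1H","7.848",""
"SYN000003","water","1H","8.29",""
"SYN000003","water","1H","7.539",""
"SYN000003","water","1H","8.331",""
"SYN000003","water","1H","7.841",""
"SYN000003","water","1H","8.553",""
"SYN000003","water","1H","7.925",""
"SYN000003","water","1H","7.557",""
"SYN000003","water","1H","7.564",""
"SYN000003","water","1H","8.034",""
"SYN000003","water","1H","8.149",""
"SYN000003","water","1H","8.548",""
"SYN000003","water","1H","7.713",""
"SYN000003","water","1H","8.127",""
"SYN000003","water","1H","7.842",""
"SYN000003","water","1H","7.979",""
"SYN000003","water","1H","8.061",""
"SYN000003","water","1H","8.319",""
"SYN000003","water","1H","7.935",""
"SYN000003","water","1H","8.026",""
"SYN000003","water","1H","8.215",""
"SYN000004","water","13C","101.908",""
"SYN000004","water","13C","106.965",""
"SYN000004","water","13C","105.734",""
"SYN000004","water","13C","107.004",""
"SYN000004","water","13C","101.753",""
"SYN000004","water","13C","95.379",""
"SYN000004","water","13C","105.704",""
"SYN000004","water","1H","4.149",""
"SYN000004","water","1H","4.088",""
"SYN000004","water","1H","9.798",""
"SYN000004","water","1H","9.205",""
"SYN000004","water","1H","5.874",""
"SYN000004","water","1H","5.182",""
"SYN000004","water","1H","3.399",""
"SYN000004","water","1H","8.9",""
"SYN000004","water","1H","3.933",""
"SYN000004","water","1H","9.439",""
"SYN000004","water","1H","9.277",""
"SYN000005","water","13C","145.633",""
"SYN000005","water","13C","150.996",""
"SYN000005","water","13C","153.957",""
"SYN000005","water","13C","153.533",""
"SYN000005","water","13C","152.383",""
"SYN000005","water","13C","151.77",""
"SYN000005","water","13C","154.473",""
"SYN000005","water","1H","4.617",""
"SYN000005","water","1H","9.996",""
"SYN000005","water","1H","9.624",""
"SYN000005","water","1H","10.562",""
"SYN000005","water","1H","4.464",""
"SYN000005","water","1H","10.244",""
"SYN000005","water","1H","9.981",""
"SYN000005","water","1H","3.643",""
"SYN000005","water","1H","10.524",""
"SYN000005","water","1H","10.436",""
"SYN000005","water","1H","9.931",""
"SYN000005","water","1H","4.446",""
"SYN000005","water","1H","4.547",""
"SYN000005","water","1H","4.959",""
"SYN000005","water","1H","4.475",""
"SYN000005","water","1H","4.598",""
"SYN000005","water","1H","10.46",""
"SYN000005","water","1H","9.88",""
"SYN000006","water","13C","38.281",""
"SYN000006","water","13C","31.995",""
"SYN000006","water","13C","46.863",""
"SYN000006","water","13C","46.526",""
"SYN000006","water","13C","53.282",""
"SYN000006","water","13C","43.002",""
"SYN000006","water","13C","50.61",""
"SYN000006","water","1H","4.89",""
"SYN000006","water","1H","4.526",""
"SYN000006","water","1H","3.861",""
"SYN000006","water","1H","4.453",""
"SYN000006","water","1H","4.626",""
"SYN000006","water","1H","4.735",""
"SYN000006","water","1H","4.713",""
"SYN000006","water","1H","4.904",""
"SYN000006","water","1H","5.149",""
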