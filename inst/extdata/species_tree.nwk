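(((((((((human:0.9,mouse:0.9)Euarchontoglires:0.05,(cow:0.8,dog:0.8)Laurasiatheria:0.15)Boreoeutheria:0.1,((sloth:0.65,armadillo:0.65)Xenarthra:0.35,(elephant:0.7,tenrec:0.7)Afrotheria:0.3)Atlantogenata:0.05)Eutheria:0.55,opossum:1.6)Theria:0.3,platypus:1.9)Mammalia:1.3,chicken:3.2)Amniota:0.3,frog:3.5)Tetrapoda:0.8,zebrafish:4.3)Gnathostomata:1.2,amphioxus:5.5)Chordata;
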