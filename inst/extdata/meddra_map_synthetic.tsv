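pt	hlt	hlgt	soc	primary_flag
Influenza	Influenza viral infections	Viral infectious disorders	Infections and infestations	Y
Herpes zoster	Herpes viral infections	Viral infectious disorders	Infections and infestations	Y
Gastroenteritis viral	Viral infections NEC	Viral infectious disorders	Infections and infestations	Y
Viral infection	Viral infections NEC	Viral infectious disorders	Infections and infestations	Y
Sepsis	Sepsis, bacteraemia, viraemia and fungaemia NEC	Infections - pathogen unspecified	Infections and infestations	Y
Pneumonia	Lower respiratory tract infections NEC	Infections - pathogen unspecified	Infections and infestations	Y
Urinary tract infection	Urinary tract infections	Infections - pathogen unspecified	Infections and infestations	Y
Meningococcal infection	Neisseria infections	Bacterial infectious disorders	Infections and infestations	Y
Headache	Headaches NEC	Headaches	Nervous system disorders	Y
Dizziness	Neurological signs and symptoms NEC	Neurological disorders NEC	Nervous system disorders	Y
Fatigue	Asthenic conditions	General system disorders NEC	General disorders and administration site conditions	Y
Pyrexia	Febrile disorders	Body temperature conditions	General disorders and administration site conditions	Y
Drug ineffective	Therapeutic and nontherapeutic responses	Therapeutic and nontherapeutic effects	General disorders and administration site conditions	Y
Anaemia	Anaemias NEC	Anaemias nonhaemolytic and marrow depression	Blood and lymphatic system disorders	Y
Haemolysis	Haemolyses NEC	Haemolyses and related conditions	Blood and lymphatic system disorders	Y
Nausea	Nausea and vomiting symptoms	Gastrointestinal signs and symptoms	Gastrointestinal disorders	Y
Arthralgia	Joint related signs and symptoms	Joint disorders	Musculoskeletal and connective tissue disorders	Y
Paroxysmal nocturnal haemoglobinuria	Haemolytic anaemias congenital	Haemolyses and related conditions	Blood and lymphatic system disorders	Y
Hypertension	Vascular hypertensive disorders NEC	Vascular hypertensive disorders	Vascular disorders	Y
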