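# Starter list of systemic anti-infective names (ATC J01 antibacterials,
# J02 antifungals, J05 antivirals); one name per line, case-insensitive.
amoxicillin
amoxicillin/clavulanate
ampicillin
azithromycin
cefepime
ceftriaxone
cefuroxime
ciprofloxacin
clarithromycin
clindamycin
doxycycline
ertapenem
gentamicin
levofloxacin
linezolid
meropenem
metronidazole
moxifloxacin
penicillin v
piperacillin/tazobactam
sulfamethoxazole/trimethoprim
tobramycin
vancomycin
amphotericin b
caspofungin
fluconazole
itraconazole
micafungin
posaconazole
voriconazole
aciclovir
acyclovir
famciclovir
ganciclovir
letermovir
oseltamivir
remdesivir
ribavirin
valaciclovir
valacyclovir
valganciclovir
zanamivir
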