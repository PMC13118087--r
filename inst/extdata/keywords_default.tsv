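label	pattern	group	surface
hip fracture	hip fracture	ofs_outcome	hip fracture
femur fracture	femur fracture	ofs_outcome	femur fracture
spine fracture	spine fracture	ofs_outcome	spine fracture
fragility fracture	fragility fracture	ofs_outcome	fragility fracture
fracture	fracture	ofs_outcome	fracture
fragility	fragility	ofs_outcome	fragility
osteoporosis	osteoporosis	ofs_pathology	osteoporosis
sarcopenia	sarcopenia	ofs_pathology	sarcopenia
malnutrition	malnutrition	ofs_pathology	malnutrition
gait	gait	ofs_pathology	gait
fall	fall	ofs_pathology	fall
frail	frail	ofs_pathology	frail
cognitive impairment	cognitive impairment	ofs_pathology	cognitive impairment
older adult	older adult	old_age	older adult
elderl*	elderl*	old_age	elderly
geriatr*	geriatr*	old_age	geriatric
sport	sport	trauma_control	sport
athlet*	athlet*	trauma_control	athlete
trauma	trauma	trauma_control	trauma
young	young	trauma_control	young
high-energy	high-energy	trauma_control	high energy
stroke	stroke	metabolic_outcome	stroke
infarction	infarction	metabolic_outcome	infarction
heart failure	heart failure	metabolic_outcome	heart failure
heart attack	heart attack	metabolic_outcome	heart attack
insulin resistance	insulin resistance	metabolic_pathology	insulin resistance
obesity	obesity	metabolic_pathology	obesity
hypertension	hypertension	metabolic_pathology	hypertension
diabetes	diabetes	metabolic_pathology	diabetes
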