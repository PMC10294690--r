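concept_id	preferred_label	code	synonyms
ataxia	ataxia	C0004134	ataxic
weakness	weakness	C9000002	weak
fatigue	fatigue	C9000003	tiredness|exhaustion
headache	headache	C9000004	cephalgia
dizziness	dizziness	C9000005	lightheadedness
vertigo	vertigo	C9000006
tremor	tremor	C9000007	shaking
dysarthria	dysarthria	C9000008	slurred speech
aphasia	aphasia	C9000009
diplopia	diplopia	C9000010	double vision
numbness	numbness	C9000011
tinnitus	tinnitus	C9000012	ringing in the ears
imbalance	imbalance	C9000013	unsteadiness
seizure	seizure	C9000014	convulsion
drowsiness	drowsiness	C9000015	somnolence
dysphagia	dysphagia	C9000016	difficulty swallowing
spasticity	spasticity	C9000017
nystagmus	nystagmus	C9000018
bradykinesia	bradykinesia	C9000019	slowness of movement
rigidity	rigidity	C9000020
myoclonus	myoclonus	C9000021
dystonia	dystonia	C9000022
chorea	chorea	C9000023
paresthesia	paresthesia	C9000024	tingling
photophobia	photophobia	C9000025	light sensitivity
insomnia	insomnia	C9000026
dysphonia	dysphonia	C9000027	hoarseness
anosmia	anosmia	C9000028	loss of smell
syncope	syncope	C9000029	fainting
hyperreflexia	hyperreflexia	C9000030	brisk reflexes|brisk ankle and knee reflex
leg_weakness	leg weakness	C9000031
memory_loss	memory loss	C9000032	forgetfulness
sensory_loss	sensory loss	C9000033
blurred_vision	blurred vision	C9000034	blurry vision
gait_instability	gait instability	C9000035	unsteady gait
facial_droop	facial droop	C9000036	facial weakness
hearing_loss	hearing loss	C9000037
neck_stiffness	neck stiffness	C9000038	stiff neck
hand_tremor	hand tremor	C9000039
muscle_cramps	muscle cramps	C9000040	cramping
arm_numbness	arm numbness	C9000041
back_pain	back pain	C9000042	low back pain
visual_loss	visual loss	C9000043	vision loss
visuospatial_neglect	visuo-spatial neglect	C9000044
loss_of_balance	loss of balance	C9000045
word_finding_difficulty	word finding difficulty	C9000046
poor_hand_coordination	poor hand coordination	C9000047
shooting_leg_pain	shooting leg pain	C9000048
decreased_grip_strength	decreased grip strength	C9000049
rapd	relative afferent pupil defect	C9000050
transient_loc	transient loss of consciousness	C9000051
decreased_pinprick	decreased sensation to pinprick	C9000052
difficulty_rising	difficulty rising from chairs	C9000053
foot_numbness_spread	numbness spreading from foot to knee	C9000054
radiating_leg_pain	shooting pain down the back of the leg	C9000055
stair_difficulty	difficulty walking up a flight of stairs	C9000056
drop_attacks	episodes of sudden loss of muscle tone	C9000057
nocturnal_hand_tingling	tingling of the hands during the night	C9000058
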