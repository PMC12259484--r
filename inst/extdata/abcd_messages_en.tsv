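behaviour	sub_behaviour	determinant	sub_determinant	bcp	conditions_for_effectiveness	application	locale
social_distancing	keeping_distance_in_public	attitude	expected_effectiveness	persuasive communication	arguments are relevant, clear and not too discrepant	Keeping 1.5 metres from others strongly reduces the chance that droplets from another person reach you.	en
social_distancing	keeping_distance_in_public	attitude	expected_risk_to_others	persuasive communication	message links behaviour to valued outcomes	Even if you feel healthy, you can carry the virus; distance protects the people around you.	en
social_distancing	keeping_distance_in_queues	perceived_norm	descriptive_community	provide information about others' behavior	the described behaviour is actually common	Most people in your community now keep their distance in queues and shops - joining them is easy.	en
social_distancing	keeping_distance_in_public	perceived_behavioural_control	skills_knowledge	planning coping responses	barriers and coping strategies are identified by the person	Plan your outings at quiet times, so keeping 1.5 metres never becomes a struggle.	en
social_distancing	keeping_distance_in_public	perceived_behavioural_control	habit_automaticity	goal setting	goal is specific and attainable	Set yourself one clear goal for today: an arm-and-a-half of space in every queue.	en
self_isolation	staying_home	attitude	perceived_importance	persuasive communication	arguments are relevant to the person's situation	Every trip you skip removes a chain of contacts through which the virus can travel.	en
self_isolation	limiting_social_visits	attitude	expected_personal_risk	fear arousal with efficacy support	risk message is paired with a doable action	Visits to friends and family are where many infections happen; meeting outdoors or online cuts that risk sharply.	en
self_isolation	limiting_social_visits	perceived_norm	injunctive_family	mobilizing social norms	the referent is valued by the person	People who care about you would rather skip a visit than put you or themselves at risk.	en
self_isolation	staying_home	perceived_behavioural_control	environmental_constraints	facilitation	practical support actually lowers the barrier	Ask a neighbour to combine shopping trips, or use delivery, to make staying home easier.	en
self_isolation	staying_home	perceived_behavioural_control	self_efficacy	guided practice	person experiences early success	Start with one home day this week; most people find the second one much easier.	en
hand_washing	washing_hands_often	attitude	expected_effectiveness	persuasive communication	arguments come from a credible source	Washing your hands with soap breaks the virus apart - it is one of the most effective things you can do.	en
hand_washing	washing_hands_often	attitude	affective_reassurance	persuasive communication	message addresses feelings, not only facts	A quick hand wash when you come home gives you one less thing to worry about.	en
hand_washing	washing_hands_thoroughly	perceived_behavioural_control	skills_knowledge	modelling	model demonstrates the skill step by step	Wash for at least 20 seconds: palms, backs, between fingers and under your nails.	en
hand_washing	washing_hands_often	perceived_behavioural_control	habit_automaticity	implementation intentions	if-then plan links a cue to the behaviour	Pick a cue - entering your home, before eating - and always wash your hands right after it.	en
hand_washing	washing_hands_often	perceived_norm	descriptive_community	provide information about others' behavior	the described behaviour is actually common	Nine out of ten people now use soap or sanitiser every time - make sure you are one of them.	en
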