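# Section header lexicon (editable): header pattern -> canonical key.
# Matched case-insensitively, line-anchored, optional trailing colon.
header	name
Patient Medical History	patient_medical_history
Current Outpatient Prescriptions	current_outpatient_prescriptions
Family History	family_history
Medications	medications
Assessment	assessment
Plan	plan
Social History	social_history
History of Present Illness	history_of_present_illness
Review of Systems	review_of_systems
Physical Exam	physical_exam
Allergies	allergies
Past Surgical History	past_surgical_history
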