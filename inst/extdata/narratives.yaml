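# English narrative registry for feedback reports. Interpretation
# sentences are glue templates; {relation} is filled with "similar to",
# "higher than" or "lower than" and {comparator_label} with the
# comparator display name. Supply a translated copy of this file to
# localize reports.
comparators:
  lymphoma_cohort: "other people with lymphoma"
  normative_population: "people from the general population"
sentences:
  green: "Your score falls in the green part. This indicates that your score is {relation} the average score of {comparator_label} with your age and sex."
  amber: "Your score falls in the yellow part. This indicates that your score is {relation} that of {comparator_label} with your age and sex."
  red: "Your score falls in the red part. This indicates that your score is {relation} the average score of {comparator_label} with your age and sex."
hads:
  green: "Your score falls in the green part, indicating no or mild symptoms."
  amber: "Your score falls in the yellow part, indicating moderate symptoms."
  red: "Your score falls in the red part, indicating severe symptoms."
gp_advice: "Because your score falls in the red part of the bar chart, we advise you to contact your general practitioner."
unavailable: "No reference scores are available for {comparator_label} on this topic; the chart shows your own score only."
not_computable: "Too many answers were missing to compute a score on this topic."
scales:
  global_qol:
    name: "General quality of life"
    description: "General quality of life summarises how you rate your overall health and quality of life. You can score between 0 and 100; the higher the score, and the closer it is to 100, the better your overall quality of life."
    context: "Quality of life covers many aspects of daily living and is experienced differently by everyone."
  physical_functioning:
    name: "Physical functioning"
    description: "Physical functioning refers to the extent to which you can carry out everyday physical activities, such as taking a walk or carrying shopping. You can score between 0 and 100; the higher the score, the better your physical functioning."
    context: "Physical fitness can be reduced during and after treatment; activity adapted to your abilities can help maintain it."
  emotional_functioning:
    name: "Emotional functioning"
    description: "Emotional functioning refers to feelings such as tension, worry, irritability and depression. You can score between 0 and 100; the higher the score, the better your emotional well-being."
    context: "Many people with cancer experience periods of worry or low mood; support is available when these feelings persist."
  cognitive_functioning:
    name: "Cognitive functioning"
    description: "Cognitive functioning is a component of quality of life. It refers, for example, to the extent to which you can concentrate or can remember things. You can score between 0 and 100; the higher the score, and the closer the score is to 100, the higher you will experience your quality of life in this part."
    context: "People with lymphoma generally score lower on cognitive functioning than the general population. Memory and concentration problems are common among people with cancer. Some also experience difficulty working under time pressure or doing different things at the same time; others must make a greater mental effort to reach the same results as before."
  social_functioning:
    name: "Social functioning"
    description: "Social functioning refers to the extent to which your physical condition or treatment has interfered with your family life and social activities. You can score between 0 and 100; the higher the score, the better your social functioning."
    context: "Illness and treatment can interfere with family life and social activities; this often improves over time."
  fatigue:
    name: "Fatigue"
    description: "Fatigue refers to feeling weak, tired or needing rest. You can score between 0 and 100; here a higher score means more fatigue."
    context: "Fatigue is one of the most commonly reported symptoms during and after treatment for lymphoma."
  tingling:
    name: "Tingling hands or feet"
    description: "This score reflects tingling in your hands or feet. You can score between 0 and 100; a higher score means more tingling."
    context: "Tingling in hands or feet (neuropathy) is a known side effect of some treatments and is a prevalent symptom among people with lymphoma."
  hads_anxiety:
    name: "Anxiety"
    description: "The anxiety score summarises feelings of tension and worry. You can score between 0 and 21; a higher score means more anxiety symptoms. Scores of 0-7 indicate no or mild symptoms, 8-10 moderate symptoms, and 11 or more severe symptoms."
    context: "Feelings of anxiety are common after a cancer diagnosis; persistent severe symptoms deserve attention from a professional."
  hads_depression:
    name: "Depressive symptoms"
    description: "The depression score summarises symptoms such as loss of interest and feeling slowed down. You can score between 0 and 21; a higher score means more depressive symptoms. Scores of 0-7 indicate no or mild symptoms, 8-10 moderate symptoms, and 11 or more severe symptoms."
    context: "Low mood can occur during and after treatment; persistent severe symptoms deserve attention from a professional."
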