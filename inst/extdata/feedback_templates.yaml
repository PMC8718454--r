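# Clinician-feedback templates and short query phrases used by
# render_feedback(). Phrases paraphrase the DASS-42 items; clause
# templates use {placeholders} filled at render time.
clauses:
  detected: "{id} is detected with '{level}' {disorder} risk due to {pp}."
  escalation: "However, a change in {pn} would shift the risk to '{level2}'."
  no_risk: "{id} shows a 'Normal' {disorder} profile."
  advice_reduce: "reduce: {phrase} (by {amount})"
  advice_increase: "increase: {phrase} (by {amount})"
query_phrases:
  Q1: getting upset by trivial things
  Q2: dryness of the mouth
  Q3: absence of positive feelings
  Q4: breathing difficulty
  Q5: being unable to get going
  Q6: over-reacting to situations
  Q7: shakiness feeling
  Q8: difficulty relaxing
  Q9: anxiety relieved only when situations end
  Q10: having nothing to look forward to
  Q11: getting upset rather easily
  Q12: using a lot of nervous energy
  Q13: feeling sad and depressed
  Q14: impatience when delayed
  Q15: faintness feeling
  Q16: lost interest in nearly everything
  Q17: feeling not worth much as a person
  Q18: feeling rather touchy
  Q19: perspiring without exertion
  Q20: feeling scared without good reason
  Q21: feeling life is not worthwhile
  Q22: finding it hard to wind down
  Q23: difficulty in swallowing
  Q24: no enjoyment from activities
  Q25: awareness of heart action without exertion
  Q26: feeling down-hearted and blue
  Q27: frequent irritability
  Q28: feeling close to panic
  Q29: difficulty calming down after upsets
  Q30: fear of trivial but unfamiliar tasks
  Q31: inability to become enthusiastic
  Q32: difficulty tolerating interruptions
  Q33: nervous tension
  Q34: feeling pretty worthless
  Q35: intolerance of being kept from tasks
  Q36: feeling terrified
  Q37: seeing nothing to be hopeful about
  Q38: feeling life is meaningless
  Q39: getting agitated
  Q42: difficulty working up initiative
  Q40: worry about panicking in public
  Q41: trembling in the hands
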