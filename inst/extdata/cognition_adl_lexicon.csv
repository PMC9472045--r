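entry_id,pattern,category,polarity
cog_imp_memory_loss,"memory (loss|lapses|problems|difficult(y|ies)|concerns?)",cognition,impaired
cog_imp_short_term,"short.term memory (loss|deficits?)",cognition,impaired
cog_imp_cog_decline,"cognitive (decline|impairment|deficits?|concerns?)",cognition,impaired
cog_imp_dementia,"dementia",cognition,impaired
cog_imp_alzheimer,"alzheimer",cognition,impaired
cog_imp_mci,"mild cognitive impairment|\bMCI\b",cognition,impaired
cog_imp_forgetful,"forgetful(ness)?",cognition,impaired
cog_imp_confusion,"confus(ed|ion)",cognition,impaired
cog_imp_disoriented,"disoriented",cognition,impaired
cog_imp_word_finding,"word.finding difficult(y|ies)",cognition,impaired
cog_int_memory_intact,"memory[^.]{0,60}intact",cognition,intact
cog_int_cognition_normal,"cognition (is |was |appears )?(grossly )?normal",cognition,intact
cog_int_cognitively_intact,"cognitively intact",cognition,intact
cog_int_no_cognitive,"no (evidence of )?cognitive (concerns?|deficits?|impairment)",cognition,intact
cog_int_fund_knowledge,"good fund of knowledge",cognition,intact
cog_int_alert_oriented,"alert and oriented x ?3",cognition,intact
adl_imp_assistance,"needs? (assistance|help) with (dressing|bathing|finances|driving|medications?)",adl,impaired
adl_imp_unable,"unable to (dress|bathe|drive|manage (finances|medications?))",adl,impaired
adl_imp_difficulty,"difficulty (dressing|bathing|driving|managing (finances|medications?))",adl,impaired
adl_imp_stopped_driving,"(stopped|no longer) driving",adl,impaired
adl_int_independent,"independent (in|with) (all )?(adls?|iadls?|dressing|bathing|finances|driving|medications?)",adl,intact
adl_int_manages,"manages (her|his|their) own (finances|medications?|affairs)",adl,intact
adl_int_continues,"continues to (work|drive|garden)",adl,intact
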