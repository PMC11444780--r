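"journal","categorized","rationale"
"Animal Behaviour","yes","precedent"
"Animal Behaviour","yes","biological"
"Animal Behaviour","yes","statistical"
"Animal Behaviour","yes","precedent"
"Animal Behaviour","yes","biological"
"Animal Behaviour","yes","precedent"
"Animal Behaviour","no",""
"Animal Behaviour","no",""
"Animal Behaviour","no",""
"Animal Behaviour","no",""
"Animal Behaviour","no",""
"Animal Behaviour","no",""
"Behavioral Ecology","yes","none"
"Behavioral Ecology","yes","statistical"
"Behavioral Ecology","yes","statistical"
"Behavioral Ecology","yes","precedent"
"Behavioral Ecology","yes","statistical"
"Behavioral Ecology","yes","biological"
"Behavioral Ecology","no",""
"Behavioral Ecology","no",""
"Behavioral Ecology","no",""
"Behavioral Ecology","no",""
"Behavioral Ecology","no",""
"Behavioral Ecology","no",""
"Ecology","yes","precedent"
"Ecology","yes","biological"
"Ecology","no",""
"Ecology","no",""
"Ecology","no",""
"Ecology","no",""
"Ecology","no",""
"Ecology","no",""
"Ecology","no",""
"Ecology","no",""
"Ecology","no",""
"Ecology","no",""
"Evolution","yes","arbitrary"
"Evolution","yes","none"
"Evolution","no",""
"Evolution","no",""
"Evolution","no",""
"Evolution","no",""
"Evolution","no",""
"Evolution","no",""
"Evolution","no",""
"Evolution","no",""
"Evolution","no",""
"Evolution","no",""
"Journal of Experimental Biology","yes","biological"
"Journal of Experimental Biology","yes","statistical"
"Journal of Experimental Biology","yes","none"
"Journal of Experimental Biology","yes","statistical"
"Journal of Experimental Biology","no",""
"Journal of Experimental Biology","no",""
"Journal of Experimental Biology","no",""
"Journal of Experimental Biology","no",""
"Journal of Experimental Biology","no",""
"Journal of Experimental Biology","no",""
"Journal of Experimental Biology","no",""
"Journal of Experimental Biology","no",""
"PNAS","yes","statistical"
"PNAS","yes","precedent"
"PNAS","no",""
"PNAS","no",""
"PNAS","no",""
"PNAS","no",""
"PNAS","no",""
"PNAS","no",""
"PNAS","no",""
"PNAS","no",""
"PNAS","no",""
"PNAS","no",""
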