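parent_node,parent_state,node,state,probability
disease,C498,edema,no,0.46
disease,C498,edema,yes,0.54
disease,C498,nausea,no,0.89
disease,C498,nausea,yes,0.11
disease,C498,diarrhea,no,0.92
disease,C498,diarrhea,yes,0.08
disease,A250,edema,no,0.61
disease,A250,edema,yes,0.39
disease,A250,nausea,no,0.81
disease,A250,nausea,yes,0.19
disease,A250,diarrhea,no,0.98
disease,A250,diarrhea,yes,0.02
disease,A320,edema,no,0.61
disease,A320,edema,yes,0.39
disease,A320,nausea,no,0.81
disease,A320,nausea,yes,0.19
disease,A320,diarrhea,no,0.98
disease,A320,diarrhea,yes,0.02
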