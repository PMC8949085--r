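parent_node,parent_state,node,state,probability
drug,Dactomicin,edema,no,0.49
drug,Dactomicin,edema,yes,0.51
drug,Dactomicin,nausea,no,0.82
drug,Dactomicin,nausea,yes,0.18
drug,Dactomicin,diarrhea,no,0.95
drug,Dactomicin,diarrhea,yes,0.05
drug,Morphine,nausea,no,0.81
drug,Morphine,nausea,yes,0.19
drug,Morphine,edema,no,0.61
drug,Morphine,edema,yes,0.39
drug,Morphine,diarrhea,no,0.98
drug,Morphine,diarrhea,yes,0.02
drug,Fludarabine,nausea,no,0.84
drug,Fludarabine,nausea,yes,0.16
drug,Fludarabine,edema,no,0.70
drug,Fludarabine,edema,yes,0.30
drug,Fludarabine,diarrhea,no,0.87
drug,Fludarabine,diarrhea,yes,0.13
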