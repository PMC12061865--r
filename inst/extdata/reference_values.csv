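condition,treatment,variant,region,observable,mean,sem,label
control,none,baseline,PFC,serotonin,66.35,0.35,control PFC extracellular serotonin (nM)
mild,none,baseline,PFC,serotonin,56.69,0.29,mild inflammation PFC serotonin
moderate,none,baseline,PFC,serotonin,54.77,0.28,moderate inflammation PFC serotonin
severe,none,baseline,PFC,serotonin,43.48,0.22,severe inflammation PFC serotonin
control,none,baseline,SCC,serotonin,65.21,1.32,control SCC extracellular serotonin (nM)
mild,none,baseline,SCC,serotonin,56.63,0.82,mild inflammation SCC serotonin
moderate,none,baseline,SCC,serotonin,54.16,0.66,moderate inflammation SCC serotonin
severe,none,baseline,SCC,serotonin,42.25,0.40,severe inflammation SCC serotonin
control,none,baseline,PFC,rate_E,4.61,0.02,control PFC population activity (Hz)
mild,none,baseline,PFC,rate_E,4.50,0.02,mild inflammation PFC activity
moderate,none,baseline,PFC,rate_E,4.46,0.02,moderate inflammation PFC activity
severe,none,baseline,PFC,rate_E,4.29,0.02,severe inflammation PFC activity
control,none,baseline,SCC,rate_E,3.79,0.02,control SCC population activity (Hz)
mild,none,baseline,SCC,rate_E,4.00,0.03,mild inflammation SCC activity
moderate,none,baseline,SCC,rate_E,4.01,0.03,moderate inflammation SCC activity
severe,none,baseline,SCC,rate_E,4.16,0.02,severe inflammation SCC activity
mild,ssri,baseline,PFC,serotonin,70.26,0.36,SSRI mild PFC serotonin
moderate,ssri,baseline,PFC,serotonin,67.72,0.35,SSRI moderate PFC serotonin
severe,ssri,baseline,PFC,serotonin,53.63,0.26,SSRI severe PFC serotonin
mild,ssri,baseline,SCC,serotonin,66.01,0.93,SSRI mild SCC serotonin
moderate,ssri,baseline,SCC,serotonin,60.92,0.76,SSRI moderate SCC serotonin
severe,ssri,baseline,SCC,serotonin,50.80,0.55,SSRI severe SCC serotonin
mild,ssri,baseline,PFC,rate_E,4.68,0.02,SSRI mild PFC activity
moderate,ssri,baseline,PFC,rate_E,4.63,0.02,SSRI moderate PFC activity
severe,ssri,baseline,PFC,rate_E,4.46,0.02,SSRI severe PFC activity
mild,ssri,baseline,SCC,rate_E,3.96,0.03,SSRI mild SCC activity
moderate,ssri,baseline,SCC,rate_E,3.88,0.03,SSRI moderate SCC activity
severe,ssri,baseline,SCC,rate_E,4.21,0.03,SSRI severe SCC activity
mild,antiinflammatory,baseline,PFC,serotonin,62.35,0.32,anti-inflammatory mild PFC serotonin
moderate,antiinflammatory,baseline,PFC,serotonin,61.23,0.33,anti-inflammatory moderate PFC serotonin
severe,antiinflammatory,baseline,PFC,serotonin,56.53,0.29,anti-inflammatory severe PFC serotonin
mild,antiinflammatory,baseline,SCC,serotonin,60.91,1.08,anti-inflammatory mild SCC serotonin
moderate,antiinflammatory,baseline,SCC,serotonin,59.45,0.83,anti-inflammatory moderate SCC serotonin
severe,antiinflammatory,baseline,SCC,serotonin,55.24,0.77,anti-inflammatory severe SCC serotonin
mild,antiinflammatory,baseline,PFC,rate_E,4.56,0.02,anti-inflammatory mild PFC activity
moderate,antiinflammatory,baseline,PFC,rate_E,4.53,0.02,anti-inflammatory moderate PFC activity
severe,antiinflammatory,baseline,PFC,rate_E,4.49,0.02,anti-inflammatory severe PFC activity
mild,antiinflammatory,baseline,SCC,rate_E,3.82,0.03,anti-inflammatory mild SCC activity
moderate,antiinflammatory,baseline,SCC,rate_E,3.84,0.03,anti-inflammatory moderate SCC activity
severe,antiinflammatory,baseline,SCC,rate_E,3.94,0.03,anti-inflammatory severe SCC activity
severe,combined,baseline,PFC,serotonin,70.07,0.39,combined severe PFC serotonin
severe,combined,baseline,SCC,serotonin,61.06,0.77,combined severe SCC serotonin
severe,combined,baseline,PFC,rate_E,4.68,0.02,combined severe PFC activity
severe,combined,baseline,SCC,rate_E,3.80,0.02,combined severe SCC activity
mild,ssri,nmda_excitotoxicity,SCC,serotonin,63.34,0.82,NMDA variant SSRI mild SCC serotonin
moderate,ssri,nmda_excitotoxicity,SCC,serotonin,62.19,0.84,NMDA variant SSRI moderate SCC serotonin
severe,ssri,nmda_excitotoxicity,SCC,serotonin,50.15,0.56,NMDA variant SSRI severe SCC serotonin
mild,ssri,nmda_excitotoxicity,SCC,rate_E,3.87,0.02,NMDA variant SSRI mild SCC activity
moderate,ssri,nmda_excitotoxicity,SCC,rate_E,3.94,0.03,NMDA variant SSRI moderate SCC activity
severe,ssri,nmda_excitotoxicity,SCC,rate_E,4.18,0.03,NMDA variant SSRI severe SCC activity
mild,antiinflammatory,nmda_excitotoxicity,SCC,serotonin,61.41,0.89,NMDA variant anti-inflammatory mild SCC serotonin
moderate,antiinflammatory,nmda_excitotoxicity,SCC,serotonin,61.63,1.02,NMDA variant anti-inflammatory moderate SCC serotonin
severe,antiinflammatory,nmda_excitotoxicity,SCC,serotonin,55.02,0.77,NMDA variant anti-inflammatory severe SCC serotonin
mild,antiinflammatory,nmda_excitotoxicity,SCC,rate_E,3.87,0.03,NMDA variant anti-inflammatory mild SCC activity
moderate,antiinflammatory,nmda_excitotoxicity,SCC,rate_E,3.90,0.03,NMDA variant anti-inflammatory moderate SCC activity
severe,antiinflammatory,nmda_excitotoxicity,SCC,rate_E,3.97,0.03,NMDA variant anti-inflammatory severe SCC activity
mild,combined,nmda_excitotoxicity,SCC,serotonin,74.84,1.28,NMDA variant combined mild SCC serotonin
moderate,combined,nmda_excitotoxicity,SCC,serotonin,69.46,0.94,NMDA variant combined moderate SCC serotonin
severe,combined,nmda_excitotoxicity,SCC,serotonin,63.55,0.86,NMDA variant combined severe SCC serotonin
mild,combined,nmda_excitotoxicity,SCC,rate_E,3.91,0.03,NMDA variant combined mild SCC activity
moderate,combined,nmda_excitotoxicity,SCC,rate_E,3.82,0.03,NMDA variant combined moderate SCC activity
severe,combined,nmda_excitotoxicity,SCC,rate_E,3.91,0.02,NMDA variant combined severe SCC activity
mild,none,receptor_reduction,SCC,serotonin,66.64,0.96,receptor variant untreated mild SCC serotonin
moderate,none,receptor_reduction,SCC,serotonin,62.18,0.81,receptor variant untreated moderate SCC serotonin
severe,none,receptor_reduction,SCC,serotonin,49.16,0.48,receptor variant untreated severe SCC serotonin
mild,none,receptor_reduction,SCC,rate_E,4.40,0.03,receptor variant untreated mild SCC activity
moderate,none,receptor_reduction,SCC,rate_E,4.38,0.02,receptor variant untreated moderate SCC activity
severe,none,receptor_reduction,SCC,rate_E,4.66,0.03,receptor variant untreated severe SCC activity
mild,ssri,receptor_reduction,SCC,serotonin,76.11,1.13,receptor variant SSRI mild SCC serotonin
moderate,ssri,receptor_reduction,SCC,serotonin,73.35,1.02,receptor variant SSRI moderate SCC serotonin
severe,ssri,receptor_reduction,SCC,serotonin,55.37,0.60,receptor variant SSRI severe SCC serotonin
mild,ssri,receptor_reduction,SCC,rate_E,4.39,0.03,receptor variant SSRI mild SCC activity
moderate,ssri,receptor_reduction,SCC,rate_E,4.36,0.03,receptor variant SSRI moderate SCC activity
severe,ssri,receptor_reduction,SCC,rate_E,4.50,0.03,receptor variant SSRI severe SCC activity
mild,antiinflammatory,receptor_reduction,SCC,serotonin,72.61,1.28,receptor variant anti-inflammatory mild SCC serotonin
moderate,antiinflammatory,receptor_reduction,SCC,serotonin,68.88,1.10,receptor variant anti-inflammatory moderate SCC serotonin
mild,antiinflammatory,receptor_reduction,SCC,rate_E,4.27,0.03,receptor variant anti-inflammatory mild SCC activity
moderate,antiinflammatory,receptor_reduction,SCC,rate_E,4.24,0.03,receptor variant anti-inflammatory moderate SCC activity
severe,antiinflammatory,receptor_reduction,SCC,rate_E,4.35,0.03,receptor variant anti-inflammatory severe SCC activity
mild,combined,receptor_reduction,SCC,serotonin,80.49,1.30,receptor variant combined mild SCC serotonin
moderate,combined,receptor_reduction,SCC,serotonin,78.27,1.24,receptor variant combined moderate SCC serotonin
severe,combined,receptor_reduction,SCC,serotonin,71.53,1.06,receptor variant combined severe SCC serotonin
mild,combined,receptor_reduction,SCC,rate_E,4.11,0.03,receptor variant combined mild SCC activity
moderate,combined,receptor_reduction,SCC,rate_E,4.12,0.03,receptor variant combined moderate SCC activity
severe,combined,receptor_reduction,SCC,rate_E,4.21,0.03,receptor variant combined severe SCC activity
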