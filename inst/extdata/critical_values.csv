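"statistic_id","tau1","tau2","alpha","n_or_grid","reps","seed","method","critical_value"
"sn",0.15,0.85,0.1,200,50000,20260901,"finite_sample",28.4554479046765
"sn",0.15,0.85,0.05,200,50000,20260901,"finite_sample",32.9055543781096
"sn",0.15,0.85,0.01,200,50000,20260901,"finite_sample",42.8435608670383
"sn",0.15,0.85,0.1,500,50000,20260901,"finite_sample",28.6706038206996
"sn",0.15,0.85,0.05,500,50000,20260901,"finite_sample",33.177219782765
"sn",0.15,0.85,0.01,500,50000,20260901,"finite_sample",43.5902037755012
"sn",0.15,0.85,0.1,1000,50000,20260901,"finite_sample",28.7733585879004
"sn",0.15,0.85,0.05,1000,50000,20260901,"finite_sample",33.2581496460362
"sn",0.15,0.85,0.01,1000,50000,20260901,"finite_sample",42.8830232657412
"sn",0.15,0.85,0.1,1000,50000,20260901,"limit_functional",27.1500235160032
"sn",0.15,0.85,0.05,1000,50000,20260901,"limit_functional",31.5530830875026
"sn",0.15,0.85,0.01,1000,50000,20260901,"limit_functional",41.3185244787964
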