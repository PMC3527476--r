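# Published maternal-circumstance effect sizes (Spanish Holstein national
# milk recording) used as planted ground truth by the recovery experiments.
# trait: my = 305-d milk yield (kg), fp = fat/protein ratio (percentage
# points), dim = lifetime days in milk (d).
# factor: lact = concurrence with maternal lactation 1/2/3+ vs heifer dam;
# mastitis = dam mastitis episode during the gestation window vs healthy;
# merit = concurrence effect planted for top-decile genetic-merit cows only.
trait,factor,level,value
my,lact,1,-18
my,lact,2,-47
my,lact,3,-91
dim,lact,1,-23
dim,lact,2,-15
dim,lact,3,-9
fp,lact,1,0.49
fp,lact,2,0.36
fp,lact,3,0.40
my,mastitis,1,-18
dim,mastitis,1,-11
my,merit,top,-90
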