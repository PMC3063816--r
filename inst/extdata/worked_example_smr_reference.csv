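view,class,smr,ci_low,ci_high
patient,1,126.8,124.1,129.4
patient,2,85.3,82.2,88.5
patient,3,72.5,68.7,76.5
patient,4,63.1,58.6,67.8
patient,"5,6",53.4,49.5,57.5
patient,7-9,49.3,44.6,54.3
patient,10-20,37.1,32.8,41.8
patient,>20,34.9,26.3,45.5
admission,1,90.4,88.5,92.3
admission,2,96.0,92.5,99.6
admission,3,99.2,94.1,104.6
admission,4,98.1,91.1,105.5
admission,"5,6",97.4,90.3,104.9
admission,7-9,95.8,86.7,105.6
admission,10-20,90.4,79.9,102.0
admission,>20,96.1,72.4,125.1
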