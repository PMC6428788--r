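section,parameter,units,comparator_mean,comparator_sd,comparator_n,planned_mean,planned_sd,planned_n,printed_p
baseline,body_weight,kg,72.7,6.4,5,70.5,5.1,5,0.559
baseline,lv_mass,g,132,14,5,120,19,5,0.309
baseline,infarct_size,g,13.4,5.0,5,19.0,5.8,5,0.141
baseline,ejection_fraction,%,52.6,8.7,5,46.9,4.4,5,0.236
baseline,end_diastolic_volume,ml,127,27,5,126,27.5,5,0.950
baseline,end_systolic_volume,ml,61,20,5,67,17,5,0.658
injection_procedure,time,min,60.2,16.7,5,69.2,11.9,5,0.355
injection_procedure,xrf_time,min,6.1,6.2,5,43.4,6.5,5,<0.001
injection_procedure,dap,Gy.cm2,11.2,18.0,5,64.2,49.0,5,0.071
injection_procedure,pvcs,count,239,100,4,283,10,4,0.42
injection_procedure,nonsustained_vts,count,41.5,11.7,4,74.3,35.0,4,0.13
per_injection,time,min/injection,5.4,1.8,5,6.0,1.4,5,0.55
per_injection,xrf_time,min/injection,0.5,0.5,5,3.7,0.8,5,<0.001
per_injection,dap,Gy.cm2/injection,0.9,1.4,5,5.4,3.6,5,0.031
per_injection,pvcs,count,21.0,7.3,4,20.3,1.1,4,0.86
per_injection,nonsustained_vts,count,3.7,0.5,4,5.2,2.1,4,0.21
total_procedure,time,min,150.2,12.4,5,69.2,11.9,5,<0.001
total_procedure,xrf_time,min,18.7,11.0,5,43.4,6.5,5,0.003
total_procedure,dap,Gy.cm2,29.4,35.7,5,69.8,49.0,5,0.174
total_procedure,pvcs,count,396,138,4,283,10,4,0.20
total_procedure,nonsustained_vts,count,120,68,4,74.3,35.0,4,0.28
endpoint,distance_to_ibz,mm,-0.7,2.2,5,0.5,3.2,5,0.52
endpoint,injection_depth,mm,2.9,1.5,5,3.4,1.0,5,0.59
endpoint,retrieved_injections,count,8.0,1.2,5,9.2,3.1,5,0.45
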