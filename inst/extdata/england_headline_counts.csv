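quantity,value
cohort_births,10653998
readmitted_infants,2077929
infant_deaths,42963
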