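model,conductivity_model,electrode_config,impedance_ohm,reported_output_current_mA,self_consistent
realistic_upper_body,isotropic,paddle,136.4,7.33,TRUE
realistic_upper_body,normalized,paddle,136.7,7.31,TRUE
realistic_upper_body,ratio_2,paddle,139.5,7.17,TRUE
realistic_upper_body,ratio_5,paddle,142.2,7.03,TRUE
realistic_upper_body,ratio_10,paddle,138.3,7.23,TRUE
realistic_upper_body,isotropic,single,348.4,2.87,TRUE
realistic_upper_body,normalized,single,348.4,2.87,TRUE
realistic_upper_body,ratio_2,single,352.1,2.84,TRUE
realistic_upper_body,ratio_5,single,354.6,2.82,TRUE
realistic_upper_body,ratio_10,single,349.7,2.86,TRUE
realistic_brain_only,isotropic,paddle,110.5,9.05,TRUE
realistic_brain_only,normalized,paddle,110.9,9.02,TRUE
realistic_brain_only,isotropic,single,327.9,3.05,TRUE
realistic_brain_only,normalized,single,327.9,3.05,TRUE
simplified_extruded_slab,isotropic,paddle,111.7,8.95,TRUE
simplified_extruded_slab,normalized,paddle,89.9,11.12,TRUE
simplified_extruded_slab,isotropic,single,467.3,2.70,FALSE
simplified_extruded_slab,normalized,single,347.2,2.88,TRUE
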