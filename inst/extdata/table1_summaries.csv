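measure,type,n1,n2,mean1,mean2,sd1,sd2,percents1,percents2
srei_total,t,51,87,16.76,11.59,8.65,7.70,,
mother_current_age,t,87,51,33.98,30.67,6.13,7.36,,
child_age,t,75,40,3.84,4.06,2.17,2.77,,
two_parent_family,chi2,87,51,,,,,72;28,49;51
education_level,chi2,87,51,,,,,43;52;5,80;18;2
rural_areas,chi2,87,51,,,,,26;74,43;57
unemployment,chi2,87,51,,,,,59;41,71;29
financial_assistance,chi2,87,51,,,,,24;76,68;32
male_child,chi2,75,40,,,,,58;42,45;55
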