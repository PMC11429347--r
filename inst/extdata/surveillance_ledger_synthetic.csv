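item_id,description,category,phase,sub_category,amount,currency,cost_basis,date
sal_setup,core team salaries,salaries,study_setup,,8000,USD,financial,
sal_prep,core team salaries,salaries,preparation,,8000,USD,financial,
sal_dc,core team salaries and per diems,salaries,data_collection,per_diem,10000,USD,financial,
sal_ar,core team salaries,salaries,analysis_reporting,,6503,USD,financial,
eq_setup,laptops and field devices,equipment,study_setup,,1000,USD,financial,
eq_prep,field devices,equipment,preparation,,1000,USD,financial,
eq_dc,field devices,equipment,data_collection,,975,USD,financial,
cons_prep,stationery and packaging,consumables,preparation,,5000,USD,financial,
cons_dc,sample packaging and labelling,consumables,data_collection,,12747,USD,financial,
trav_prep,training and coordination travel,travel,preparation,,5000,USD,financial,
trav_dc,field transport and accommodation,travel,data_collection,,16660,USD,financial,
lab_ar,contracted pharmacopeial testing of 1274 samples,laboratory,analysis_reporting,,481704,USD,financial,
od_setup,design and sampling-frame services,other_direct,study_setup,,20000,USD,financial,
od_prep,recruitment and stakeholder services,other_direct,preparation,,30000,USD,financial,
od_dc_med,medicine purchases at outlets,other_direct,data_collection,medicine_purchase,20000,USD,financial,
od_dc_srv,barcoding and mobile data for field team,other_direct,data_collection,,12734,USD,financial,
ind_setup,overheads,indirect,study_setup,overhead,8296,USD,financial,
ind_prep,overheads,indirect,preparation,overhead,5356,USD,financial,
ind_dc,overheads,indirect,data_collection,overhead,27392,USD,financial,
ind_ar,overheads,indirect,analysis_reporting,overhead,10156,USD,financial,
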