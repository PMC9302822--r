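"day","mean_bone","max_bone","mean_cartilage","max_cartilage","mean_connective","mean_perfusion","min_perfusion","mean_E","mean_eps_dis","max_eps_dis","mean_eps_hyd","ifm","contact_iterations"
1,0,0,4.23279852957403,6.1162982689747,95.767201470426,2.05479155579981,0,3,1.80544838074168,6.43251035795862,-0.175437550115341,0.638753514322069,0
2,0,0,8.17299924892087,12.2325965379494,91.8270007510791,4.10954758783057,0,4.56613545594239,1.80024071027204,6.42220847886947,-0.154927376147686,0.631194756307229,0
3,0.226869920723209,5.1432192556649,11.8699553753675,18.3488948069241,87.9031747039092,7.23745932973458,0,6.02400972210072,1.79134767741425,6.40105216426284,-0.139082040917716,0.624103242741092,0
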