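year,cohort_deaths,pct_hes_only,ons_deaths,pct_ons_unlinked
1998,2337,33,4357,28
1999,2396,24,4584,26
2000,2269,27,4358,27
2001,1948,33,4320,30
2002,2104,32,4246,29
2003,2571,12,3967,14
2004,2585,10,3864,13
2005,2602,9,3870,11
2006,2651,9,3931,11
2007,2651,10,3969,11
2008,2668,10,4106,12
2009,2577,8,3985,8
2010,2546,6,3834,7
2011,2444,6,3656,7
2012,2342,4,3509,8
2013,2171,5,3181,8
2014,2075,4,2934,8
2015,2026,4,2924,7
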