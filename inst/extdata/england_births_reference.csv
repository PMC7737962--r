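year,cohort_births,singleton_births
1998,546804,584928
1999,542734,572611
2000,526254,556172
2001,527602,547292
2002,540030,549003
2003,554104,572711
2004,571530,589248
2005,577964,595019
2006,592768,616588
2007,602801,635561
2008,631027,652280
2009,630170,649416
2010,649431,665746
2011,650223,666320
2012,653116,672505
2013,626619,646941
2014,614637,640663
2015,616184,643363
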