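year,consumption
1991,131.3
1992,172.9
1993,218.4
1994,303.6
1995,405.1
1996,345.7
1997,432.3
1998,472.7
1999,501.7
2000,510.0
2001,505.2
2002,521.4
2003,541.5
2004,556.6
2005,561.4
2006,569.2
2007,606.5
2008,608.0
2009,634.0
2010,652.0
2011,644.9
2012,668.0
2013,705.2
2014,729.7
2015,749.6
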