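query,type,bgp_count,tp_count,total_vertices,join_vertices,ratio,mean_join_degree,clauses
SQ1,simple,2,4,10,2,0.20,2.0,UNION
SQ2,simple,1,7,15,4,0.266,2.5,
SQ3,simple,1,6,13,4,0.307,2.250,
SQ4,simple,1,5,11,3,0.272,2.333,
SQ5,simple,2,5,12,3,0.250,2.0,OPTIONAL
SQ6,simple,1,3,7,2,0.285,2.0,
SQ7,simple,1,4,9,3,0.333,2.0,
SQ8,simple,1,3,7,2,0.285,2.0,
SQ9,simple,1,8,14,2,0.117,4.5,DISTINCT
SQ10,simple,1,8,17,2,0.117,4.5,DISTINCT
CQ1,complex,2,8,18,4,0.222,2.5,"DISTINCT,OPTIONAL,FILTER"
CQ2,complex,2,8,19,4,0.210,2.25,"OPTIONAL,FILTER"
CQ3,complex,1,10,19,4,0.210,3.75,"DISTINCT,FILTER,REGEX"
CQ4,complex,1,6,13,4,0.307,2.25,
CQ5,complex,2,10,22,3,0.136,3.666,OPTIONAL
CQ6,complex,2,12,24,6,0.25,3.0,OPTIONAL
CQ7,complex,1,8,17,4,0.235,2.75,
CQ8,complex,1,6,13,2,0.153,3.5,
CQ9,complex,1,9,19,5,0.263,2.6,FILTER
CQ10,complex,2,9,20,3,0.15,3.333,OPTIONAL
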