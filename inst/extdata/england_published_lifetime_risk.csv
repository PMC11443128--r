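period,sex,event_definition,band,risk,ci_low,ci_high
2016-2019,M,first,0-4,3.1,2.9,3.3
2016-2019,M,first,5-9,5.1,4.7,5.6
2016-2019,M,first,10-14,7.1,6.5,7.8
2016-2019,M,first,15-19,9.4,8.6,10.2
2016-2019,M,first,20-24,11.8,10.8,12.8
2016-2019,M,first,25-29,14.3,13,15.5
2016-2019,M,first,30-34,16.8,15.4,18.2
2016-2019,M,first,35-39,19.4,17.7,20.9
2016-2019,M,first,40-44,22,20.2,23.9
2016-2019,M,first,45-49,24.9,22.8,27
2016-2019,M,first,50-54,28.1,25.6,30.6
2016-2019,M,first,55-59,31.7,28.9,34.5
2016-2019,M,first,60-64,35.8,32.6,39
2016-2019,M,first,65-69,40.2,36.7,43.8
2016-2019,M,first,70-74,44.8,40.8,48.8
2016-2019,M,first,75-79,49.4,45,53.8
2016-2019,M,first,80-84,53.5,48.9,58.2
2016-2019,M,first,85-89,56.9,52,61.8
2016-2019,M,first,90+,59.1,54.2,64.1
2016-2019,M,all,0-4,4.5,4.5,4.6
2016-2019,M,all,5-9,7.3,7.1,7.5
2016-2019,M,all,10-14,10,9.7,10.3
2016-2019,M,all,15-19,13,12.7,13.3
2016-2019,M,all,20-24,16.2,15.8,16.6
2016-2019,M,all,25-29,19.6,19.1,20.1
2016-2019,M,all,30-34,23.1,22.5,23.6
2016-2019,M,all,35-39,26.7,26.1,27.3
2016-2019,M,all,40-44,30.5,29.8,31.2
2016-2019,M,all,45-49,34.8,34,35.6
2016-2019,M,all,50-54,39.6,38.8,40.5
2016-2019,M,all,55-59,45.2,44.4,46.1
2016-2019,M,all,60-64,51.5,50.6,52.3
2016-2019,M,all,65-69,58.1,57.1,59
2016-2019,M,all,70-74,64.5,63.5,65.6
2016-2019,M,all,75-79,70.5,69.3,71.6
2016-2019,M,all,80-84,75.1,73.9,76.4
2016-2019,M,all,85-89,78.3,77,79.7
2016-2019,M,all,90+,80,78.6,81.4
2016-2019,F,first,0-4,2.1,1.9,2.2
2016-2019,F,first,5-9,3.6,3.3,3.9
2016-2019,F,first,10-14,5.1,4.7,5.6
2016-2019,F,first,15-19,7.4,6.8,8
2016-2019,F,first,20-24,10.8,9.8,11.9
2016-2019,F,first,25-29,15.4,13.8,16.9
2016-2019,F,first,30-34,20.2,18.2,22.3
2016-2019,F,first,35-39,24.3,21.8,26.9
2016-2019,F,first,40-44,27.5,24.6,30.4
2016-2019,F,first,45-49,30.6,27.3,33.9
2016-2019,F,first,50-54,33.7,30.1,37.3
2016-2019,F,first,55-59,36.9,33,40.8
2016-2019,F,first,60-64,40.3,36.1,44.4
2016-2019,F,first,65-69,43.9,39.5,48.3
2016-2019,F,first,70-74,47.8,43.1,52.5
2016-2019,F,first,75-79,51.8,46.9,56.7
2016-2019,F,first,80-84,55.4,50.4,60.4
2016-2019,F,first,85-89,58.3,53.2,63.4
2016-2019,F,first,90+,60.2,55.1,65.4
2016-2019,F,all,0-4,3.1,3,3.1
2016-2019,F,all,5-9,5.2,5,5.3
2016-2019,F,all,10-14,7.3,7.1,7.5
2016-2019,F,all,15-19,10.3,10,10.6
2016-2019,F,all,20-24,15.1,14.6,15.5
2016-2019,F,all,25-29,21.3,20.7,21.8
2016-2019,F,all,30-34,27.9,27.6,28.4
2016-2019,F,all,35-39,33.6,32.9,34.2
2016-2019,F,all,40-44,38.2,37.5,38.9
2016-2019,F,all,45-49,42.8,42,43.6
2016-2019,F,all,50-54,47.5,46.6,48.3
2016-2019,F,all,55-59,52.1,51.2,53
2016-2019,F,all,60-64,56.9,56,57.8
2016-2019,F,all,65-69,61.9,60.9,62.8
2016-2019,F,all,70-74,66.9,65.8,67.9
2016-2019,F,all,75-79,71.6,70.4,72.8
2016-2019,F,all,80-84,75.4,74.1,76.7
2016-2019,F,all,85-89,78.1,76.7,79.5
2016-2019,F,all,90+,79.5,78.1,80.9
2020,F,first,90+,40.8,39.3,42.2
2020,M,first,90+,40.4,38.8,41.9
2020,F,all,90+,72.2,70.8,73.7
2020,M,all,90+,75.4,73.8,77
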