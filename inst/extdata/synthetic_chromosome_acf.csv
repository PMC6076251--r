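lag_s,acf
0,6.9200756361226e-07
0.0847457627118644,5.0907427799554e-07
0.169491525423729,3.87655936180319e-07
0.254237288135593,3.19372803068731e-07
0.338983050847458,2.90399551095723e-07
0.423728813559322,2.41837700067567e-07
0.508474576271186,2.31231258027982e-07
0.593220338983051,2.0473292420278e-07
0.677966101694915,1.81560260276165e-07
0.76271186440678,1.58638434928893e-07
0.847457627118644,1.45352290695871e-07
0.932203389830508,1.35608971364024e-07
1.01694915254237,1.15453948235674e-07
1.10169491525424,1.13575238213091e-07
1.1864406779661,9.74894946881482e-08
1.27118644067797,9.65750926823043e-08
1.35593220338983,8.67068204147929e-08
1.44067796610169,8.69139044641903e-08
1.52542372881356,6.97300897826981e-08
1.61016949152542,6.29933938952976e-08
1.69491525423729,5.70495307262807e-08
1.77966101694915,5.64238760487745e-08
1.86440677966102,4.86356986080148e-08
1.94915254237288,4.97640830213505e-08
2.03389830508475,4.37878561233028e-08
2.11864406779661,3.96405179181047e-08
2.20338983050847,3.49111963609173e-08
2.28813559322034,2.78008199244034e-08
2.3728813559322,2.87690837964949e-08
2.45762711864407,2.08783744250716e-08
2.54237288135593,1.76756904489772e-08
2.6271186440678,1.66709982095248e-08
2.71186440677966,2.59486888826028e-08
2.79661016949153,8.43476407840935e-09
2.88135593220339,1.17057833318062e-08
2.96610169491525,1.96220788946683e-08
3.05084745762712,1.3568468021474e-08
3.13559322033898,2.43560265702757e-08
3.22033898305085,8.18251567583778e-09
3.30508474576271,8.95776710007038e-09
3.38983050847458,-9.83147755532847e-10
3.47457627118644,9.66392184053008e-09
3.5593220338983,1.49182783663194e-08
3.64406779661017,1.89301994352257e-09
3.72881355932203,1.34852651914997e-08
3.8135593220339,4.27450539529072e-09
3.89830508474576,-9.12258266890085e-09
3.98305084745763,1.17065659434099e-08
4.06779661016949,1.01437121831598e-08
4.15254237288136,6.20024860604714e-09
4.23728813559322,9.77035049325951e-09
4.32203389830508,2.30684046075813e-09
4.40677966101695,-2.12288933966474e-09
4.49152542372881,6.74902572120962e-09
4.57627118644068,4.09977811666471e-09
4.66101694915254,6.51402988352832e-09
4.74576271186441,1.41305316753804e-09
4.83050847457627,5.34470550166689e-09
4.91525423728813,1.24524148943711e-08
5,2.33532657110212e-09
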