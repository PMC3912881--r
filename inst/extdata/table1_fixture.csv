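item,label,condition,median,mean,sd,p
1,The simulation provided a realistic experience,recital,4.0,3.42,1.08,ns
1,The simulation provided a realistic experience,audition,4.0,3.67,0.50,0.005
2,The steps involved closely approximated a real performance situation,recital,4.0,3.75,0.75,0.013
2,The steps involved closely approximated a real performance situation,audition,3.5,3.50,1.00,ns
3,I behaved and presented myself as in a real performance,recital,4.0,3.42,1.24,ns
3,I behaved and presented myself as in a real performance,audition,4.0,3.67,0.98,0.046
4,The interaction with the backstage manager was realistic,recital,4.5,4.00,1.20,0.018
4,The interaction with the backstage manager was realistic,audition,4.0,3.92,1.24,0.029
5,The CCTV footage in the backstage area was realistic,recital,3.0,2.83,1.40,ns
5,The CCTV footage in the backstage area was realistic,audition,4.0,3.58,1.56,ns
6,The sounds heard in the backstage area were realistic,recital,3.5,3.42,1.08,ns
6,The sounds heard in the backstage area were realistic,audition,4.0,4.00,1.12,0.028
7,The decor of the backstage area was realistic,recital,4.0,3.67,0.49,0.005
7,The decor of the backstage area was realistic,audition,3.5,3.42,1.08,ns
8,The transition from backstage on to stage was realistic,recital,4.0,4.08,0.90,0.008
8,The transition from backstage on to stage was realistic,audition,4.0,3.67,0.98,0.046
9,The interaction with the audience was realistic,recital,3.5,3.42,1.08,ns
9,The interaction with the audience was realistic,audition,3.5,3.42,1.08,ns
10,The spot-lights in the performance space were realistic,recital,4.5,4.08,1.08,0.012
10,The spot-lights in the performance space were realistic,audition,3.5,3.42,1.37,ns
11,The curtains in the performance space were realistic,recital,3.0,3.33,0.98,ns
11,The curtains in the performance space were realistic,audition,3.0,3.17,0.93,ns
12,Could be used to enhance my musical skills,recital,4.0,4.25,0.86,0.005
12,Could be used to enhance my musical skills,audition,4.0,4.25,0.75,0.004
13,Could be used to enhance my technical skills,recital,5.0,4.33,0.98,0.005
13,Could be used to enhance my technical skills,audition,4.5,4.33,0.77,0.004
14,Could be used to enhance my communicative/presentational skills,recital,3.0,3.58,1.31,ns
14,Could be used to enhance my communicative/presentational skills,audition,4.0,4.17,0.83,0.006
15,Could be used to help me manage performance anxiety,recital,4.0,4.17,0.93,0.007
15,Could be used to help me manage performance anxiety,audition,4.0,4.33,0.77,0.003
16,Could be used to highlight strengths in my performance,recital,4.5,4.33,0.88,0.004
16,Could be used to highlight strengths in my performance,audition,4.0,4.17,0.71,0.004
17,Could be used to highlight weaknesses in my performance,recital,4.5,4.25,0.88,0.006
17,Could be used to highlight weaknesses in my performance,audition,4.5,4.42,0.66,0.003
18,I would recommend the simulation for developing performance skills,recital,5.0,4.33,1.10,0.005
18,I would recommend the simulation for developing performance skills,audition,4.5,4.42,0.66,0.003
19,I would recommend the simulation for teaching performance skills,recital,5.0,4.42,1.16,0.004
19,I would recommend the simulation for teaching performance skills,audition,4.5,4.33,0.77,0.004
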